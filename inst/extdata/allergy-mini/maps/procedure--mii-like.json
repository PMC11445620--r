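{
  "resourceType": "StructureMap",
  "id": "procedure--mii-like",
  "url": "urn:sctfhir:structuremap:procedure--mii-like",
  "name": "procedure--mii-like",
  "status": "active",
  "group": [
    {
      "name": "mapping",
      "rule": [
        {
          "name": "rule-01",
          "source": [
            {
              "context": "source",
              "value": "Superconcept"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.code"
            }
          ]
        },
        {
          "name": "rule-02",
          "source": [
            {
              "context": "source",
              "value": "260686004"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.method"
            }
          ]
        },
        {
          "name": "rule-03",
          "source": [
            {
              "context": "source",
              "value": "405813007"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.bodySite"
            }
          ]
        },
        {
          "name": "rule-04",
          "source": [
            {
              "context": "source",
              "value": "405814001"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.bodySite"
            }
          ]
        },
        {
          "name": "rule-05",
          "source": [
            {
              "context": "source",
              "value": "363701004"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.usedCode"
            }
          ]
        },
        {
          "name": "rule-06",
          "source": [
            {
              "context": "source",
              "value": "424361007"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.usedCode"
            }
          ]
        },
        {
          "name": "rule-07",
          "source": [
            {
              "context": "source",
              "value": "363700003"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.outcome"
            }
          ]
        },
        {
          "name": "rule-08",
          "source": [
            {
              "context": "source",
              "value": "424226004"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Device.type"
            }
          ]
        },
        {
          "name": "rule-09",
          "source": [
            {
              "context": "source",
              "value": "425391005"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Device.type"
            }
          ]
        },
        {
          "name": "rule-10",
          "source": [
            {
              "context": "source",
              "value": "363703001"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.category"
            }
          ]
        },
        {
          "name": "rule-11",
          "source": [
            {
              "context": "source",
              "value": "260507000"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.access"
            }
          ]
        },
        {
          "name": "rule-12",
          "source": [
            {
              "context": "source",
              "value": "424876005"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.approach"
            }
          ]
        },
        {
          "name": "rule-13",
          "source": [
            {
              "context": "source",
              "value": "363702006"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Procedure.extension(http://hl7.org/fhir/StructureDefinition/procedure-hasFocus)"
            }
          ],
          "documentation": "extension"
        }
      ]
    },
    {
      "name": "references",
      "rule": [
        {
          "name": "ref-01",
          "source": [
            {
              "context": "source",
              "value": "Procedure.usedReference"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Device"
            }
          ]
        },
        {
          "name": "ref-02",
          "source": [
            {
              "context": "source",
              "value": "Procedure.subject"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Patient"
            }
          ]
        }
      ]
    },
    {
      "name": "profiles",
      "rule": [
        {
          "name": "profile-01",
          "source": [
            {
              "context": "source",
              "value": "Procedure"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "MII_PR_Prozedur_Procedure"
            }
          ]
        },
        {
          "name": "profile-02",
          "source": [
            {
              "context": "source",
              "value": "Device"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "MII_PR_Geraet_Device"
            }
          ]
        }
      ]
    }
  ]
}
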