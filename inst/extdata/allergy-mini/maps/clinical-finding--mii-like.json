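{
  "resourceType": "StructureMap",
  "id": "clinical-finding--mii-like",
  "url": "urn:sctfhir:structuremap:clinical-finding--mii-like",
  "name": "clinical-finding--mii-like",
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
              "value": "Condition.code"
            }
          ]
        },
        {
          "name": "rule-02",
          "source": [
            {
              "context": "source",
              "value": "246075003"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Observation.valueCodeableConcept"
            }
          ]
        },
        {
          "name": "rule-03",
          "source": [
            {
              "context": "source",
              "value": "363698007"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Condition.bodySite"
            }
          ]
        },
        {
          "name": "rule-04",
          "source": [
            {
              "context": "source",
              "value": "116676008"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Condition.evidence.code"
            }
          ]
        },
        {
          "name": "rule-05",
          "source": [
            {
              "context": "source",
              "value": "370135005"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Condition.extension(http://hl7.org/fhir/StructureDefinition/condition-related)"
            }
          ],
          "documentation": "extension"
        },
        {
          "name": "rule-06",
          "source": [
            {
              "context": "source",
              "value": "263502005"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Condition.extension(http://hl7.org/fhir/StructureDefinition/condition-diseaseCourse)"
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
              "value": "Observation.focus"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Condition"
            }
          ]
        },
        {
          "name": "ref-02",
          "source": [
            {
              "context": "source",
              "value": "Condition.subject"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "Patient"
            }
          ]
        },
        {
          "name": "ref-03",
          "source": [
            {
              "context": "source",
              "value": "Observation.subject"
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
              "value": "Condition"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "MII_PR_Diagnose_Condition"
            }
          ]
        },
        {
          "name": "profile-02",
          "source": [
            {
              "context": "source",
              "value": "Observation"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "MII_PR_Befund_Observation"
            }
          ]
        }
      ]
    }
  ]
}
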