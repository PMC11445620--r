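{
  "resourceType": "StructureMap",
  "id": "clinical-finding--nashp-like",
  "url": "urn:sctfhir:structuremap:clinical-finding--nashp-like",
  "name": "clinical-finding--nashp-like",
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
              "value": "AllergyIntolerance.code"
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
          "name": "ref-02",
          "source": [
            {
              "context": "source",
              "value": "AllergyIntolerance.patient"
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
              "value": "KBV_PR_Base_Condition"
            }
          ]
        },
        {
          "name": "profile-02",
          "source": [
            {
              "context": "source",
              "value": "AllergyIntolerance"
            }
          ],
          "target": [
            {
              "context": "target",
              "value": "KBV_PR_Base_AllergyIntolerance"
            }
          ]
        }
      ]
    }
  ]
}
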