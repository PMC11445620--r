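- id: allergic-reaction
  name: Allergic reaction
  constraint: << 400001
  profileSets:
  - nashp-like
  - mii-like
- id: allergy
  name: Allergies
  constraint: << 400010
  profileSets:
  - nashp-like
  - mii-like
- id: disease-due-to-allergy
  name: Disease due to allergy
  constraint: << 400020
  profileSets:
  - nashp-like
  - mii-like
- id: clinical-finding
  name: Clinical finding (general)
  constraint: << 100002 MINUS << 400001 MINUS << 400010 MINUS << 400020
  profileSets:
  - nashp-like
  - mii-like
- id: procedure
  name: Procedure
  constraint: << 100003
  profileSets:
  - nashp-like
  - mii-like
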