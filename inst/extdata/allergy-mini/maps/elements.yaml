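allergic-reaction:
- Superconcept
- '246075003'
- '363698007'
- '116676008'
- '370135005'
- '263502005'
- '719722006'
- '246454002'
- '42752001'
allergy:
- Superconcept
- '246075003'
- '363698007'
- '116676008'
- '370135005'
- '263502005'
- '719722006'
- '246454002'
- '42752001'
disease-due-to-allergy:
- Superconcept
- '246075003'
- '363698007'
- '116676008'
- '370135005'
- '263502005'
- '719722006'
- '246454002'
- '42752001'
clinical-finding:
- Superconcept
- '246075003'
- '363698007'
- '116676008'
- '370135005'
- '263502005'
procedure:
- Superconcept
- '260686004'
- '405813007'
- '405814001'
- '363701004'
- '363700003'
- '424361007'
- '424226004'
- '425391005'
- '363703001'
- '260507000'
- '424876005'
- '363702006'
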