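'246075003':
  attributeId: '246075003'
  domainConstraint: << 100002
  rangeConstraint: << 100005
  maxPerGroup: 1.0
  groupedAllowed: yes
'363698007':
  attributeId: '363698007'
  domainConstraint: << 100002
  rangeConstraint: << 100004
  maxPerGroup: 1.0
  groupedAllowed: yes
'116676008':
  attributeId: '116676008'
  domainConstraint: << 100002
  rangeConstraint: << 100006
  maxPerGroup: 1.0
  groupedAllowed: yes
'370135005':
  attributeId: '370135005'
  domainConstraint: << 100002
  rangeConstraint: << 360001
  maxPerGroup: 1.0
  groupedAllowed: yes
'263502005':
  attributeId: '263502005'
  domainConstraint: << 100002
  rangeConstraint: << 340003
  maxPerGroup: 1.0
  groupedAllowed: no
'719722006':
  attributeId: '719722006'
  domainConstraint: << 100002
  rangeConstraint: << 360001
  maxPerGroup: 1.0
  groupedAllowed: yes
'246454002':
  attributeId: '246454002'
  domainConstraint: << 100002
  rangeConstraint: << 370001
  maxPerGroup: 1.0
  groupedAllowed: yes
'42752001':
  attributeId: '42752001'
  domainConstraint: << 100002
  rangeConstraint: << 100002
  maxPerGroup: 1.0
  groupedAllowed: yes
'260686004':
  attributeId: '260686004'
  domainConstraint: << 100003
  rangeConstraint: << 100010
  maxPerGroup: 1.0
  groupedAllowed: yes
'363704007':
  attributeId: '363704007'
  domainConstraint: << 100003
  rangeConstraint: << 100004
  maxPerGroup: 1.0
  groupedAllowed: yes
'405813007':
  attributeId: '405813007'
  domainConstraint: << 100003
  rangeConstraint: << 100004
  maxPerGroup: 1.0
  groupedAllowed: yes
'405814001':
  attributeId: '405814001'
  domainConstraint: << 100003
  rangeConstraint: << 100004
  maxPerGroup: 1.0
  groupedAllowed: yes
'363701004':
  attributeId: '363701004'
  domainConstraint: << 100003
  rangeConstraint: << 100005
  maxPerGroup: 1.0
  groupedAllowed: yes
'363700003':
  attributeId: '363700003'
  domainConstraint: << 100003
  rangeConstraint: << 100006
  maxPerGroup: 1.0
  groupedAllowed: yes
'424361007':
  attributeId: '424361007'
  domainConstraint: << 100003
  rangeConstraint: << 100005
  maxPerGroup: 1.0
  groupedAllowed: yes
'405815000':
  attributeId: '405815000'
  domainConstraint: << 100003
  rangeConstraint: << 100008
  maxPerGroup: 1.0
  groupedAllowed: yes
'424226004':
  attributeId: '424226004'
  domainConstraint: << 100003
  rangeConstraint: << 100008
  maxPerGroup: 1.0
  groupedAllowed: yes
'425391005':
  attributeId: '425391005'
  domainConstraint: << 100003
  rangeConstraint: << 330002
  maxPerGroup: 1.0
  groupedAllowed: yes
'363703001':
  attributeId: '363703001'
  domainConstraint: << 100003
  rangeConstraint: << 380001
  maxPerGroup: 1.0
  groupedAllowed: yes
'260507000':
  attributeId: '260507000'
  domainConstraint: << 100003
  rangeConstraint: << 390001
  maxPerGroup: 1.0
  groupedAllowed: yes
'424876005':
  attributeId: '424876005'
  domainConstraint: << 100003
  rangeConstraint: << 395001
  maxPerGroup: 1.0
  groupedAllowed: yes
'363702006':
  attributeId: '363702006'
  domainConstraint: << 100003
  rangeConstraint: << 100002
  maxPerGroup: 1.0
  groupedAllowed: yes
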