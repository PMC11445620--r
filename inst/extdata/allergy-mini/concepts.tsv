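id	effectiveTime	active	moduleId	definitionStatusId
100001	20230430	1	900000000000207008	primitive
100002	20230430	1	900000000000207008	primitive
100003	20230430	1	900000000000207008	primitive
100004	20230430	1	900000000000207008	primitive
100005	20230430	1	900000000000207008	primitive
100006	20230430	1	900000000000207008	primitive
100007	20230430	1	900000000000207008	primitive
100008	20230430	1	900000000000207008	primitive
100009	20230430	1	900000000000207008	primitive
100010	20230430	1	900000000000207008	primitive
246075003	20230430	1	900000000000207008	primitive
363698007	20230430	1	900000000000207008	primitive
116676008	20230430	1	900000000000207008	primitive
370135005	20230430	1	900000000000207008	primitive
263502005	20230430	1	900000000000207008	primitive
719722006	20230430	1	900000000000207008	primitive
246454002	20230430	1	900000000000207008	primitive
42752001	20230430	1	900000000000207008	primitive
260686004	20230430	1	900000000000207008	primitive
363704007	20230430	1	900000000000207008	primitive
405813007	20230430	1	900000000000207008	primitive
405814001	20230430	1	900000000000207008	primitive
363701004	20230430	1	900000000000207008	primitive
363700003	20230430	1	900000000000207008	primitive
424361007	20230430	1	900000000000207008	primitive
405815000	20230430	1	900000000000207008	primitive
424226004	20230430	1	900000000000207008	primitive
425391005	20230430	1	900000000000207008	primitive
363703001	20230430	1	900000000000207008	primitive
260507000	20230430	1	900000000000207008	primitive
424876005	20230430	1	900000000000207008	primitive
363702006	20230430	1	900000000000207008	primitive
300001	20230430	1	900000000000207008	primitive
300002	20230430	1	900000000000207008	primitive
300003	20230430	1	900000000000207008	primitive
300004	20230430	1	900000000000207008	primitive
310001	20230430	1	900000000000207008	primitive
310002	20230430	1	900000000000207008	primitive
310003	20230430	1	900000000000207008	primitive
320001	20230430	1	900000000000207008	primitive
320002	20230430	1	900000000000207008	primitive
320003	20230430	1	900000000000207008	primitive
330002	20230430	1	900000000000207008	primitive
330001	20230430	1	900000000000207008	primitive
330003	20230430	1	900000000000207008	primitive
340003	20230430	1	900000000000207008	primitive
340001	20230430	1	900000000000207008	primitive
340002	20230430	1	900000000000207008	primitive
360001	20230430	1	900000000000207008	primitive
360002	20230430	1	900000000000207008	primitive
360003	20230430	1	900000000000207008	primitive
370001	20230430	1	900000000000207008	primitive
370002	20230430	1	900000000000207008	primitive
380001	20230430	1	900000000000207008	primitive
380002	20230430	1	900000000000207008	primitive
390001	20230430	1	900000000000207008	primitive
390002	20230430	1	900000000000207008	primitive
395001	20230430	1	900000000000207008	primitive
395002	20230430	1	900000000000207008	primitive
350001	20230430	1	900000000000207008	primitive
350002	20230430	1	900000000000207008	primitive
350003	20230430	1	900000000000207008	primitive
400001	20230430	1	900000000000207008	primitive
400010	20230430	1	900000000000207008	primitive
400020	20230430	1	900000000000207008	primitive
400002	20230430	1	900000000000207008	fullyDefined
400004	20230430	1	900000000000207008	fullyDefined
400003	20230430	1	900000000000207008	fullyDefined
400005	20230430	1	900000000000207008	fullyDefined
400006	20230430	1	900000000000207008	fullyDefined
400007	20230430	1	900000000000207008	fullyDefined
400011	20230430	1	900000000000207008	fullyDefined
400021	20230430	1	900000000000207008	fullyDefined
400022	20230430	1	900000000000207008	fullyDefined
500001	20230430	1	900000000000207008	primitive
500002	20230430	1	900000000000207008	fullyDefined
500003	20230430	1	900000000000207008	fullyDefined
500004	20230430	1	900000000000207008	fullyDefined
500005	20230430	1	900000000000207008	fullyDefined
999999	20230430	0	900000000000207008	primitive
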