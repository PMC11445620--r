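id	effectiveTime	active	moduleId	sourceId	destinationId	relationshipGroup	typeId
7000000	20230430	1	900000000000207008	100002	100001	0	116680003
7000001	20230430	1	900000000000207008	100003	100001	0	116680003
7000002	20230430	1	900000000000207008	100004	100001	0	116680003
7000003	20230430	1	900000000000207008	100005	100001	0	116680003
7000004	20230430	1	900000000000207008	100006	100004	0	116680003
7000005	20230430	1	900000000000207008	100007	100001	0	116680003
7000006	20230430	1	900000000000207008	100008	100001	0	116680003
7000007	20230430	1	900000000000207008	100009	100001	0	116680003
7000008	20230430	1	900000000000207008	100010	100009	0	116680003
7000009	20230430	1	900000000000207008	246075003	100007	0	116680003
7000010	20230430	1	900000000000207008	363698007	100007	0	116680003
7000011	20230430	1	900000000000207008	116676008	100007	0	116680003
7000012	20230430	1	900000000000207008	370135005	100007	0	116680003
7000013	20230430	1	900000000000207008	263502005	100007	0	116680003
7000014	20230430	1	900000000000207008	719722006	100007	0	116680003
7000015	20230430	1	900000000000207008	246454002	100007	0	116680003
7000016	20230430	1	900000000000207008	42752001	100007	0	116680003
7000017	20230430	1	900000000000207008	260686004	100007	0	116680003
7000018	20230430	1	900000000000207008	363704007	100007	0	116680003
7000019	20230430	1	900000000000207008	405813007	363704007	0	116680003
7000020	20230430	1	900000000000207008	405814001	363704007	0	116680003
7000021	20230430	1	900000000000207008	363701004	100007	0	116680003
7000022	20230430	1	900000000000207008	363700003	100007	0	116680003
7000023	20230430	1	900000000000207008	424361007	100007	0	116680003
7000024	20230430	1	900000000000207008	405815000	100007	0	116680003
7000025	20230430	1	900000000000207008	424226004	405815000	0	116680003
7000026	20230430	1	900000000000207008	425391005	424226004	0	116680003
7000027	20230430	1	900000000000207008	363703001	100007	0	116680003
7000028	20230430	1	900000000000207008	260507000	100007	0	116680003
7000029	20230430	1	900000000000207008	424876005	100007	0	116680003
7000030	20230430	1	900000000000207008	363702006	100007	0	116680003
7000031	20230430	1	900000000000207008	300001	100005	0	116680003
7000032	20230430	1	900000000000207008	300002	300001	0	116680003
7000033	20230430	1	900000000000207008	300003	100005	0	116680003
7000034	20230430	1	900000000000207008	300004	100005	0	116680003
7000035	20230430	1	900000000000207008	310001	100004	0	116680003
7000036	20230430	1	900000000000207008	310002	310001	0	116680003
7000037	20230430	1	900000000000207008	310003	100004	0	116680003
7000038	20230430	1	900000000000207008	320001	100006	0	116680003
7000039	20230430	1	900000000000207008	320002	100006	0	116680003
7000040	20230430	1	900000000000207008	320003	100006	0	116680003
7000041	20230430	1	900000000000207008	330002	100008	0	116680003
7000042	20230430	1	900000000000207008	330001	330002	0	116680003
7000043	20230430	1	900000000000207008	330003	100008	0	116680003
7000044	20230430	1	900000000000207008	340003	100009	0	116680003
7000045	20230430	1	900000000000207008	340001	340003	0	116680003
7000046	20230430	1	900000000000207008	340002	340003	0	116680003
7000047	20230430	1	900000000000207008	360001	100009	0	116680003
7000048	20230430	1	900000000000207008	360002	360001	0	116680003
7000049	20230430	1	900000000000207008	360003	360001	0	116680003
7000050	20230430	1	900000000000207008	370001	100009	0	116680003
7000051	20230430	1	900000000000207008	370002	370001	0	116680003
7000052	20230430	1	900000000000207008	380001	100009	0	116680003
7000053	20230430	1	900000000000207008	380002	380001	0	116680003
7000054	20230430	1	900000000000207008	390001	100009	0	116680003
7000055	20230430	1	900000000000207008	390002	390001	0	116680003
7000056	20230430	1	900000000000207008	395001	100009	0	116680003
7000057	20230430	1	900000000000207008	395002	395001	0	116680003
7000058	20230430	1	900000000000207008	350001	100010	0	116680003
7000059	20230430	1	900000000000207008	350002	100010	0	116680003
7000060	20230430	1	900000000000207008	350003	100010	0	116680003
7000061	20230430	1	900000000000207008	400001	100002	0	116680003
7000062	20230430	1	900000000000207008	400010	100002	0	116680003
7000063	20230430	1	900000000000207008	400020	100002	0	116680003
7000064	20230430	1	900000000000207008	400002	100002	0	116680003
7000065	20230430	1	900000000000207008	400002	320001	0	116676008
7000066	20230430	1	900000000000207008	400004	400001	0	116680003
7000067	20230430	1	900000000000207008	400004	300001	0	246075003
7000068	20230430	1	900000000000207008	400003	400004	0	116680003
7000069	20230430	1	900000000000207008	400003	300002	0	246075003
7000070	20230430	1	900000000000207008	400005	400002	0	116680003
7000071	20230430	1	900000000000207008	400005	320001	0	116676008
7000072	20230430	1	900000000000207008	400005	310001	0	363698007
7000073	20230430	1	900000000000207008	400006	400001	0	116680003
7000074	20230430	1	900000000000207008	400006	300003	0	246075003
7000075	20230430	1	900000000000207008	400007	100002	0	116680003
7000076	20230430	1	900000000000207008	400007	320003	0	116676008
7000077	20230430	1	900000000000207008	400011	400010	0	116680003
7000078	20230430	1	900000000000207008	400011	300001	0	246075003
7000079	20230430	1	900000000000207008	400021	400020	0	116680003
7000080	20230430	1	900000000000207008	400021	360002	0	370135005
7000081	20230430	1	900000000000207008	400021	320002	0	116676008
7000082	20230430	1	900000000000207008	400022	400020	0	116680003
7000083	20230430	1	900000000000207008	400022	360003	0	370135005
7000084	20230430	1	900000000000207008	500001	100003	0	116680003
7000085	20230430	1	900000000000207008	500002	100003	0	116680003
7000086	20230430	1	900000000000207008	500002	350003	0	260686004
7000087	20230430	1	900000000000207008	500002	330001	0	425391005
7000088	20230430	1	900000000000207008	500003	100003	0	116680003
7000089	20230430	1	900000000000207008	500003	350002	0	260686004
7000090	20230430	1	900000000000207008	500004	100003	0	116680003
7000091	20230430	1	900000000000207008	500004	350001	0	260686004
7000092	20230430	1	900000000000207008	500005	500004	0	116680003
7000093	20230430	1	900000000000207008	500005	350001	0	260686004
7000094	20230430	1	900000000000207008	500005	310001	0	405813007
7000095	20230430	0	900000000000207008	999999	100002	0	116680003
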