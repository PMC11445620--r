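id	active	conceptId	typeId	term
8000001	1	100001	900000000000003001	SNOMED CT concept (synthetic root)
8000002	1	100002	900000000000003001	Clinical finding (finding)
8000003	1	100003	900000000000003001	Procedure (procedure)
8000004	1	100004	900000000000003001	Body structure (body structure)
8000005	1	100005	900000000000003001	Substance (substance)
8000006	1	100006	900000000000003001	Morphologic abnormality (morphologic abnormality)
8000007	1	100007	900000000000003001	Attribute (attribute)
8000008	1	100008	900000000000003001	Device (physical object)
8000009	1	100009	900000000000003001	Qualifier value (qualifier value)
8000010	1	100010	900000000000003001	Action (qualifier value)
8000011	1	246075003	900000000000003001	Causative agent (attribute)
8000012	1	363698007	900000000000003001	Finding site (attribute)
8000013	1	116676008	900000000000003001	Associated morphology (attribute)
8000014	1	370135005	900000000000003001	Pathological process (attribute)
8000015	1	263502005	900000000000003001	Clinical course (attribute)
8000016	1	719722006	900000000000003001	Has realization (attribute)
8000017	1	246454002	900000000000003001	Occurrence (attribute)
8000018	1	42752001	900000000000003001	Due to (attribute)
8000019	1	260686004	900000000000003001	Method (attribute)
8000020	1	363704007	900000000000003001	Procedure site (attribute)
8000021	1	405813007	900000000000003001	Procedure site - Direct (attribute)
8000022	1	405814001	900000000000003001	Procedure site - Indirect (attribute)
8000023	1	363701004	900000000000003001	Direct substance (attribute)
8000024	1	363700003	900000000000003001	Direct morphology (attribute)
8000025	1	424361007	900000000000003001	Using substance (attribute)
8000026	1	405815000	900000000000003001	Procedure device (attribute)
8000027	1	424226004	900000000000003001	Using device (attribute)
8000028	1	425391005	900000000000003001	Using access device (attribute)
8000029	1	363703001	900000000000003001	Has intent (attribute)
8000030	1	260507000	900000000000003001	Access (attribute)
8000031	1	424876005	900000000000003001	Surgical approach (attribute)
8000032	1	363702006	900000000000003001	Has focus (attribute)
8000033	1	300001	900000000000003001	Nut substance (substance)
8000034	1	300002	900000000000003001	Tree nut substance (substance)
8000035	1	300003	900000000000003001	Drug substance (substance)
8000036	1	300004	900000000000003001	Contrast medium (substance)
8000037	1	310001	900000000000003001	Skin structure (body structure)
8000038	1	310002	900000000000003001	Lip structure (body structure)
8000039	1	310003	900000000000003001	Vascular structure (body structure)
8000040	1	320001	900000000000003001	Swelling morphology (morphologic abnormality)
8000041	1	320002	900000000000003001	Inflammation morphology (morphologic abnormality)
8000042	1	320003	900000000000003001	Fracture morphology (morphologic abnormality)
8000043	1	330002	900000000000003001	Access device (physical object)
8000044	1	330001	900000000000003001	Catheter device (physical object)
8000045	1	330003	900000000000003001	Imaging scanner (physical object)
8000046	1	340003	900000000000003001	Course qualifier (qualifier value)
8000047	1	340001	900000000000003001	Acute course (qualifier value)
8000048	1	340002	900000000000003001	Chronic course (qualifier value)
8000049	1	360001	900000000000003001	Process qualifier (qualifier value)
8000050	1	360002	900000000000003001	Allergic process (qualifier value)
8000051	1	360003	900000000000003001	Autoimmune process (qualifier value)
8000052	1	370001	900000000000003001	Life period qualifier (qualifier value)
8000053	1	370002	900000000000003001	Childhood period (qualifier value)
8000054	1	380001	900000000000003001	Intent qualifier (qualifier value)
8000055	1	380002	900000000000003001	Diagnostic intent (qualifier value)
8000056	1	390001	900000000000003001	Access qualifier (qualifier value)
8000057	1	390002	900000000000003001	Percutaneous access (qualifier value)
8000058	1	395001	900000000000003001	Approach qualifier (qualifier value)
8000059	1	395002	900000000000003001	Lateral approach (qualifier value)
8000060	1	350001	900000000000003001	Excision action (qualifier value)
8000061	1	350002	900000000000003001	Imaging action (qualifier value)
8000062	1	350003	900000000000003001	Insertion action (qualifier value)
8000063	1	400001	900000000000003001	Allergic reaction (finding)
8000064	1	400010	900000000000003001	Allergy to substance (finding)
8000065	1	400020	900000000000003001	Allergic disease (finding)
8000066	1	400002	900000000000003001	Swelling (finding)
8000067	1	400004	900000000000003001	Allergic reaction caused by nut (finding)
8000068	1	400003	900000000000003001	Allergic reaction caused by tree nut (finding)
8000069	1	400005	900000000000003001	Swelling of skin (finding)
8000070	1	400006	900000000000003001	Allergic reaction caused by drug (finding)
8000071	1	400007	900000000000003001	Fracture finding (finding)
8000072	1	400011	900000000000003001	Allergy to nut (finding)
8000073	1	400021	900000000000003001	Allergic inflammatory disease (finding)
8000074	1	400022	900000000000003001	Autoimmune disease (finding)
8000075	1	500001	900000000000003001	Allergy testing procedure (procedure)
8000076	1	500002	900000000000003001	Catheterization procedure (procedure)
8000077	1	500003	900000000000003001	Imaging procedure (procedure)
8000078	1	500004	900000000000003001	Excision procedure (procedure)
8000079	1	500005	900000000000003001	Excision of skin (procedure)
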