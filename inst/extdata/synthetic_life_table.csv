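"age","sex","qx"
18,"female",0.000136936148550558
19,"female",0.000149832012253657
20,"female",0.000163942334683755
21,"female",0.000179381486621558
22,"female",0.000196274609634119
23,"female",0.000214758630405932
24,"female",0.000234983370593922
25,"female",0.000257112761202241
26,"female",0.000281326171319931
27,"female",0.000307819861991515
28,"female",0.000336808577004802
29,"female",0.000368527283490001
30,"female",0.000403233076438499
31,"female",0.000441207262578343
32,"female",0.000482757640497195
33,"female",0.000528220995494236
34,"female",0.000577965829382958
35,"female",0.000632395347371186
36,"female",0.000691950726228375
37,"female",0.000757114690230233
38,"female",0.000828415423865357
39,"female",0.000906430853018225
40,"female",0.000991793329329519
41,"female",0.00108519475570273
42,"female",0.00118739219450169
43,"female",0.00129921400389604
44,"female",0.00142156655209273
45,"female",0.00155544156387535
46,"female",0.00170192415899862
47,"female",0.00186220164759291
48,"female",0.00203757315386963
49,"female",0.00222946014613227
50,"female",0.0024394179584436
51,"female",0.00266914839733765
52,"female",0.00292051353575983
53,"female",0.00319555080604138
54,"female",0.00349648951424394
55,"female",0.00382576890973064
56,"female",0.00418605795642619
57,"female",0.00458027696602112
58,"female",0.00501162126846763
59,"female",0.00548358711162737
60,"female",0.006
61,"female",0.00656504570223126
62,"female",0.00718330417873086
63,"female",0.00785978670439948
64,"female",0.00859997648736204
65,"female",0.00940987311294101
66,"female",0.0102960411731092
67,"female",0.0112656634755861
68,"female",0.0123265992638633
69,"female",0.0134874479200588
70,"female",0.0147576186669417
71,"female",0.0161474068340956
72,"female",0.0176680773063931
73,"female",0.019331955831171
74,"female",0.0211525289241923
75,"female",0.0231445531841818
76,"female",0.0253241749019793
77,"female",0.0277090609337987
78,"female",0.0303185418993832
79,"female",0.033173768865744
80,"female",0.0362978847864777
81,"female",0.0397162120862585
82,"female",0.0434564579109661
83,"female",0.0475489387070969
84,"female",0.0520268259507807
85,"female",0.0569264150181512
86,"female",0.0622874193763911
87,"female",0.0681532924800087
88,"female",0.0745715799814653
89,"female",0.0815943051109855
90,"female",0.089278390349237
91,"female",0.0976861188107306
92,"female",0.106885639077673
93,"female",0.116951517576187
94,"female",0.127965342972161
95,"female",0.140016387485656
96,"female",0.153202330484109
97,"female",0.167630050219419
98,"female",0.183416490126301
99,"female",0.200689606703669
100,"female",0.219589406662068
101,"female",0.24026908174372
102,"female",0.262896250413444
103,"female",0.287654316484915
104,"female",0.314743955694594
105,"female",0.344384742272677
106,"female",0.37681692869521
107,"female",0.412303393043079
108,"female",0.451131769752139
109,"female",0.49361678102521
110,"female",0.540102787803131
18,"male",0.00022822691425093
19,"male",0.000249720020422762
20,"male",0.000273237224472926
21,"male",0.000298969144369263
22,"male",0.000327124349390198
23,"male",0.000357931050676553
24,"male",0.000391638950989871
25,"male",0.000428521268670402
26,"male",0.000468876952199885
27,"male",0.000513033103319191
28,"male",0.000561347628341337
29,"male",0.000614212139150001
30,"male",0.000672055127397498
31,"male",0.000735345437630571
32,"male",0.000804596067495324
33,"male",0.000880368325823726
34,"male",0.00096327638230493
35,"male",0.00105399224561864
36,"male",0.00115325121038063
37,"male",0.00126185781705039
38,"male",0.00138069237310893
39,"male",0.00151071808836371
40,"male",0.00165298888221587
41,"male",0.00180865792617122
42,"male",0.00197898699083615
43,"male",0.00216535667316007
44,"male",0.00236927758682122
45,"male",0.00259240260645892
46,"male",0.0028365402649977
47,"male",0.00310366941265485
48,"male",0.00339595525644939
49,"male",0.00371576691022046
50,"male",0.00406569659740599
51,"male",0.00444858066222941
52,"male",0.00486752255959972
53,"male",0.00532591801006897
54,"male",0.0058274825237399
55,"male",0.00637628151621773
56,"male",0.00697676326071031
57,"male",0.00763379494336853
58,"male",0.00835270211411272
59,"male",0.00913931185271228
60,"male",0.01
61,"male",0.0109417428370521
62,"male",0.0119721736312181
63,"male",0.0130996445073325
64,"male",0.0143332941456034
65,"male",0.0156831218549017
66,"male",0.0171600686218486
67,"male",0.0187761057926434
68,"male",0.0205443321064389
69,"male",0.0224790798667647
70,"male",0.0245960311115695
71,"male",0.0269123447234926
72,"male",0.0294467955106552
73,"male",0.032219926385285
74,"male",0.0352542148736538
75,"male",0.0385742553069697
76,"male",0.0422069581699655
77,"male",0.0461817682229978
78,"male",0.0505309031656387
79,"male",0.05528961477624
80,"male",0.0604964746441294
81,"male",0.0661936868104308
82,"male",0.0724274298516101
83,"male",0.0792482311784949
84,"male",0.0867113765846346
85,"male",0.0948773583635853
86,"male",0.103812365627318
87,"male",0.113588820800015
88,"male",0.124285966635775
89,"male",0.135990508518309
90,"male",0.148797317248728
91,"male",0.162810198017884
92,"male",0.178142731796122
93,"male",0.194919195960311
94,"male",0.213275571620269
95,"male",0.233360645809427
96,"male",0.255337217473515
97,"male",0.279383417032365
98,"male",0.305694150210502
99,"male",0.334482677839449
100,"male",0.36598234443678
101,"male",0.400448469572867
102,"male",0.43816041735574
103,"male",0.479423860808192
104,"male",0.524573259490991
105,"male",0.573974570454462
106,"male",0.628028214492017
107,"male",0.687172321738464
108,"male",0.751886282920231
109,"male",0.822694635042017
110,"male",0.900171313005218
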