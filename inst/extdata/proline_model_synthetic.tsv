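# max_distance=60 n_pairs=73528
distance	observed	expected	lor
1	0.052429006636927428	0.049787490495793459	0.074581912441094828
2	0.049232945272549233	0.047446506237778158	0.053322191664437024
3	0.048158524643673158	0.045215593952495421	0.090970780139956145
4	0.045071265368295074	0.043089578107841697	0.06486898102566295
5	0.042473615493417473	0.041063526522785394	0.048709389879955142
6	0.039794364051789793	0.03913273892511452	0.024188032053040015
7	0.03978076379066478	0.0372927360471937	0.093176329327853302
8	0.035918289631160921	0.035539249234433447	0.015305448191988095
9	0.034435861168534435	0.033868210542364399	0.023979993508407387
10	0.033592644978783594	0.032275743299342345	0.057695072607276993
11	0.030586987270155588	0.030758153112990478	-0.0080508660317752719
12	0.029988575780654989	0.029311919299514405	0.032925570690462071
13	0.027526928517027528	0.027933686716006798	-0.021162353004940061
14	0.027758132956152759	0.02662025797679312	0.060385981388639931
15	0.025446088564900445	0.025368586035761181	0.004400799651876057
16	0.025119682297900119	0.02417576711746601	0.055256549448700724
17	0.023528451746273528	0.023039033980610808	0.030326163045520601
18	0.021610814927646611	0.021955749498275907	-0.022845308074876145
19	0.020522794037645523	0.020923400540002263	-0.027890184841540832
20	0.018904362963768906	0.019939592141536538	-0.076916665702183223
21	0.018360352518768362	0.019002041948711971	-0.049560699319689046
22	0.018346752257643345	0.018108574922575366	0.018851683745555983
23	0.016973125884016973	0.017257118293476509	-0.023939288285291887
24	0.016061908388641064	0.016445696752413908	-0.034066815695211784
25	0.01578990316614079	0.015672427868481168	0.010773633828367863
26	0.014062670003264062	0.014935517721782881	-0.086876710667092835
27	0.014470677837014471	0.014233256741688769	0.023866696574333233
28	0.013709063214013708	0.013564015740771103	0.015345626628231092
29	0.012675443368512675	0.012926242135224551	-0.028266710162234195
30	0.011818626917636819	0.01231845634300007	-0.059759045946943153
31	0.011301816994886301	0.011739248351296845	-0.054785303935827902
32	0.011233815689261234	0.011187274445449154	0.0059894427684440005
33	0.0098873898378848881	0.010661254091619389	-0.1087155326762361
34	0.0093977804373843975	0.010159966966065413	-0.11250374415240089
35	0.0087177673811337179	0.0096822501240903368	-0.15138365586674749
36	0.0088945707757588938	0.0092269953021069488	-0.052935934932235307
37	0.007928952235882929	0.0087931463465577928	-0.14924924517465007
38	0.008078555108258079	0.0083796967637262219	-0.052800755519209423
39	0.0077385485801327383	0.007985687384754166	-0.045353591958222861
40	0.0066641279512566643	0.0076102041404496473	-0.19151905320706303
41	0.007031335001632031	0.007252375940721833	-0.04465507983952819
42	0.0062153193341312153	0.0069113726537240053	-0.15314375304122207
43	0.0061337177673811338	0.0065864031800162998	-0.10272904278873962
44	0.0056169078446306172	0.0062767136172803993	-0.16023325256950408
45	0.0055217060167555218	0.0059815855113284624	-0.11541386474860256
46	0.0051544989663801543	0.0057003341893487889	-0.14521430170751615
47	0.0047056903492547061	0.0054323071715215018	-0.20715867018671208
48	0.0047192906103797191	0.0051768826573192856	-0.13351360319000466
49	0.0047464911326297468	0.0049334680829815659	-0.055740787503442323
50	0.004120879120879121	0.0047014987468155557	-0.19016858818497273
51	0.0040664780763790664	0.0044804364991350111	-0.13985945540464789
52	0.0038624741595038627	0.0042697684937974363	-0.14463256804289942
53	0.0035904689370035905	0.0040690059984434283	-0.18050412613395747
54	0.0032776629311282775	0.0038776832606779907	-0.24252746720727814
55	0.0032504624088782507	0.0036953564275634845	-0.18506855340132014
56	0.0033048634533783048	0.0035216025159174927	-0.091641415721117087
57	0.003128060058753128	0.003356018431026802	-0.10148242632735185
58	0.002516048308127516	0.003198220031500987	-0.34610957470024406
59	0.0028424545751278424	0.0030478412380961334	-0.10065046108050207
60	0.0022032423022522031	0.0029045331844412556	-0.39867814822158931
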