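trait_id	L_o	L_p	L_a
g00001	1.59508201853048	2.15657673658291	2.05348845144324
g00002	2.02537204340894	3.39679705887006	4.63453447480917
g00003	2.82427522108462	3.03793572993692	3.30997799744192
g00004	0.548649723258537	0.301184612192507	0.257409672308889
g00005	1.64382218133158	2.84719676734022	1.53898428599338
g00006	0.18437028694291	0.29364722156165	0.170657176706209
g00007	0.460680221034047	0.62659476512978	0.313323831228728
g00008	0.416544908529307	0.402691789966081	0.39377219420347
g00009	0.0919439487041586	0.145277613507044	0.0957870291167212
g00010	1.06206145208497	2.00913828523874	1.53882780027536
g00011	1.24917093526057	1.23189079028838	1.38687082885867
g00012	0.674145115335564	1.01142245518816	0.6208730060258
g00013	2.11018813881343	3.15012524109326	4.56539272254363
g00014	0.489684216999595	0.433495667014527	0.435594135595129
g00015	0.254766814720198	0.279818784832095	0.272726205767524
g00016	1.5523629779514	2.88186309556184	4.2469433571695
g00017	0.466638082732999	0.305708274632213	0.122918486715687
g00018	4.16923954234049	3.87404595152086	3.89215611327468
g00019	0.622687678253746	1.10610879598812	0.910620324749427
g00020	1.93696398070798	3.4305570701204	1.58064879553071
g00021	1.36093685747474	2.52039658094939	2.35059085753277
g00022	0.460741505051361	0.486953434309724	0.462751211136215
g00023	4.7563464705146	3.05245082270787	1.32616367897467
g00024	1.98802247862128	3.66722045157479	4.60521188949238
g00025	1.09120929603896	1.04087266847728	0.951296708925832
g00026	1.30604571904973	0.817368053594805	1.92132954450288
g00027	1.96592640318568	1.82093607518836	1.7815377581113
g00028	1.11302791656958	1.60560171690801	1.50830959643617
g00029	0.0502299772845578	0.0514939428319957	0.0551322537229224
g00030	1.28707296226856	2.47455290615678	2.56495548427685
g00031	0.692583093089796	0.95025513049648	0.346644557795533
g00032	1.22193468275337	0.176937509612648	0.955795493025411
g00033	1.79069452183158	1.8418550031514	1.7666767873842
g00034	4.11417476188256	2.43622870342035	4.26926035985745
g00035	0.481802253281209	0.47280941307873	0.484589458421291
g00036	3.67438174308006	1.6997045257704	1.5879886537796
g00037	1.41268974685653	1.38191956129465	1.22023154905548
g00038	2.88165554623846	2.84259545139424	2.81506794771527
g00039	2.44929605389477	0.908103888808328	0.84328462735337
g00040	2.05486142455921	3.22509318570397	2.46882728709958
g00041	0.351854274432314	0.356221535324748	0.381665277689404
g00042	0.899996144383509	0.83831429914308	0.906365199283419
g00043	1.82728448126812	2.03789741293496	2.09277780617993
g00044	0.380549888657547	0.169426747542893	0.043640884596643
g00045	0.587962175711643	0.552070703966724	0.553250642399682
g00046	1.772994711975	2.50334815092544	3.18208877829609
g00047	2.12225877554003	3.51989153990402	3.20219272690034
g00048	1.59525869599239	2.04205293159105	1.30937044624823
g00049	0.402318754824167	0.254355437837198	0.0408093454632377
g00050	0.339981721495941	0.23436834115014	0.428141213069224
g00051	4.49522220933084	4.61937926964683	4.85464355330926
g00052	1.29914195738039	1.14035878568734	1.10242551996913
g00053	1.09358397818127	1.19387894739295	1.28225723798078
g00054	0.886121370342081	0.391292035501083	1.07537466526634
g00055	0.314069413842627	0.301176175074889	0.303488849553259
g00056	1.81392016254726	1.16986895312555	1.903116297491
g00057	0.823468125124453	0.136036366605383	0.527728904726388
g00058	0.833496944569995	0.91144949923858	0.900395521250826
g00059	2.50087885591853	2.44405493944992	2.37578330543724
g00060	2.27140330728008	3.05032353104924	2.25519331994554
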