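M1	M2	M3	M4	M5	expl_active	expl_collaborative	expl_passive	conf_active	conf_collaborative	conf_passive	flag	flag_category
1	1	1	1	1	0.868561	0.013433	0.965462	0.132716	0.250897	0.988444
1	1	1	1	2	0.986465	0.566994	0.065148	0.651998	0.589635	0.438021
1	1	1	1	3	0.837806	0.943782	0.044112	0.869598	0.816498	0.109900
1	1	1	2	1	0.003995	0.558877	0.998703	0.040347	0.743055	0.946179
1	1	1	2	2	0.206284	0.377986	0.945128	0.063365	0.643754	0.942566
1	1	1	2	3	0.167299	0.870319	0.760671	0.950949	0.766104	0.141515
1	1	2	1	1	0.387803	0.863616	0.492469	0.161224	0.974986	0.549439
1	1	2	1	2	0.736882	0.012917	0.979951	0.975624	0.845271	0.018431
1	1	2	1	3	0.999647	0.802734	0.004485	0.996089	0.357889	0.178549
1	1	2	2	1	0.000526	0.719929	1.000000	0.060949	0.046314	0.999981
1	1	2	2	2	0.428826	0.380616	0.855444	0.557708	0.357889	0.786593
1	1	2	2	3	1.000000	0.312849	1.000000	0.481830	0.924178	0.436117
1	2	1	1	1	0.857129	0.683738	0.290362	0.851363	0.441130	0.517129
1	2	1	1	2	0.999620	0.531546	0.014243	0.972254	0.923865	0.007423
1	2	1	1	3	0.967847	0.997609	0.000459	0.946666	0.936227	0.014773
1	2	1	2	1	0.404697	0.895093	0.584079	0.024306	0.890320	0.978174
1	2	1	2	2	0.835002	0.575279	0.370051	0.387784	0.052811	0.998311
1	2	1	2	3	0.869697	0.769805	0.284715	0.777927	0.269913	0.861121
1	2	2	1	1	0.490653	0.406689	0.752028	0.717236	0.823456	0.238753
1	2	2	1	2	0.980595	0.860401	0.007893	0.999999	0.718093	0.000058	T1	3
1	2	2	1	3	0.999730	0.946691	0.000071	0.999980	0.915213	0.000060	T2	3
1	2	2	2	1	0.122222	0.613263	0.908054	0.018876	0.421608	0.997229
1	2	2	2	2	0.506892	0.784709	0.393508	0.772922	0.589417	0.366223
1	2	2	2	3	0.978426	0.434567	0.216913	0.915578	0.889245	0.042856
2	1	1	1	1	0.010568	0.240021	0.999566	0.010179	0.650267	0.978838
2	1	1	1	2	0.120891	0.218840	0.981613	0.303068	0.058791	0.988485
2	1	1	1	3	0.771296	0.051227	0.952478	0.620639	0.103562	0.923111
2	1	1	2	1	0.000000	0.912684	0.999979	0.000000	0.836925	0.999998	T3	1
2	1	1	2	2	0.000008	0.897191	0.999555	0.010179	0.949048	0.869418
2	1	1	2	3	0.463636	0.093064	0.988886	0.319816	0.287885	0.970943
2	1	2	1	1	0.013963	0.206085	0.999954	0.029721	0.349747	0.995546
2	1	2	1	2	0.456875	0.044917	0.981564	0.079130	0.395506	0.968858
2	1	2	1	3	0.273647	0.928973	0.509020	0.996089	0.104609	0.473831
2	1	2	2	1	0.000145	0.411609	0.999990	0.007815	0.772473	0.980082
2	1	2	2	2	0.155768	0.233927	0.983029	0.099956	0.405697	0.971317
2	1	2	2	3	1.000000	0.068152	0.801432	0.077756	0.467936	0.993923
2	2	1	1	1	0.600728	0.713610	0.400621	0.034337	0.257264	0.997223
2	2	1	1	2	0.974082	0.757745	0.031957	0.996559	0.302793	0.092598
2	2	1	1	3	0.975795	0.121327	0.519333	0.855271	0.936875	0.036585
2	2	1	2	1	0.059371	0.977447	0.530169	0.114972	0.136279	0.997053
2	2	1	2	2	0.213526	0.769220	0.693151	0.087146	0.837020	0.789409
2	2	1	2	3	0.794185	0.029025	0.961348	0.961883	0.180994	0.682467
2	2	2	1	1	0.075093	0.803607	0.782896	0.106104	0.469835	0.936655
2	2	2	1	2	0.999969	0.467800	0.001904	0.999989	0.244953	0.006359
2	2	2	1	3	0.999868	0.745509	0.001138	0.991909	0.868168	0.004507
2	2	2	2	1	0.001424	0.431570	0.999327	0.000080	0.312023	0.999994	T4	1
2	2	2	2	2	0.750593	0.667267	0.246865	0.135057	0.574359	0.589893
2	2	2	2	3	0.490653	0.798727	0.380271	0.842434	0.711906	0.194625
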