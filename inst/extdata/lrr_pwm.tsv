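aa	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24
A	0.025717	0.078	0.078	0.025717	0.078	0.078	0.025717	0.078	0.025717	0.078	0.078	0.024497	0.078	0.025717	0.025194	0.025265	0.078	0.024668	0.024684	0.078	0.078	0.025717	0.025265	0.078
R	0.016881	0.0512	0.0512	0.016881	0.0512	0.0512	0.016881	0.0512	0.016881	0.0512	0.0512	0.01608	0.0512	0.016881	0.016537	0.016584	0.0512	0.016192	0.016203	0.0512	0.0512	0.016881	0.016584	0.0512
N	0.014771	0.0448	0.0448	0.014771	0.0448	0.0448	0.014771	0.0448	0.014771	0.0448	0.0448	0.7	0.0448	0.014771	0.01447	0.014511	0.0448	0.014168	0.014177	0.0448	0.0448	0.014771	0.014511	0.0448
D	0.017672	0.0536	0.0536	0.017672	0.0536	0.0536	0.017672	0.0536	0.017672	0.0536	0.0536	0.016834	0.0536	0.017672	0.017313	0.017361	0.0536	0.016951	0.016962	0.0536	0.0536	0.017672	0.017361	0.0536
C	0.00633	0.0192	0.0192	0.00633	0.0192	0.0192	0.00633	0.0192	0.00633	0.0192	0.0192	0.00603	0.0192	0.00633	0.006202	0.006219	0.0192	0.006072	0.006076	0.0192	0.0192	0.00633	0.006219	0.0192
Q	0.014045	0.0426	0.0426	0.014045	0.0426	0.0426	0.014045	0.0426	0.014045	0.0426	0.0426	0.013379	0.0426	0.014045	0.01376	0.013798	0.0426	0.013472	0.013481	0.0426	0.0426	0.014045	0.013798	0.0426
E	0.020739	0.0629	0.0629	0.020739	0.0629	0.0629	0.020739	0.0629	0.020739	0.0629	0.0629	0.019755	0.0629	0.020739	0.020317	0.020374	0.0629	0.019892	0.019905	0.0629	0.0629	0.020739	0.020374	0.0629
G	0.024332	0.0738	0.0738	0.024332	0.0738	0.0738	0.024332	0.0738	0.024332	0.0738	0.0738	0.023178	0.0738	0.024332	0.023837	0.7	0.0738	0.02334	0.023354	0.0738	0.0738	0.024332	0.7	0.0738
H	0.007221	0.0219	0.0219	0.007221	0.0219	0.0219	0.007221	0.0219	0.007221	0.0219	0.0219	0.006878	0.0219	0.007221	0.007074	0.007094	0.0219	0.006926	0.00693	0.0219	0.0219	0.007221	0.007094	0.0219
I	0.016947	0.0514	0.0514	0.016947	0.0514	0.0514	0.016947	0.0514	0.016947	0.0514	0.0514	0.016143	0.0514	0.016947	0.016602	0.016649	0.0514	0.7	0.016266	0.0514	0.0514	0.016947	0.016649	0.0514
L	0.7	0.0901	0.0901	0.7	0.0901	0.0901	0.7	0.0901	0.7	0.0901	0.0901	0.028298	0.0901	0.7	0.029102	0.029184	0.0901	0.028495	0.028513	0.0901	0.0901	0.7	0.029184	0.0901
K	0.018925	0.0574	0.0574	0.018925	0.0574	0.0574	0.018925	0.0574	0.018925	0.0574	0.0574	0.018028	0.0574	0.018925	0.01854	0.018592	0.0574	0.018153	0.018165	0.0574	0.0574	0.018925	0.018592	0.0574
M	0.007385	0.0224	0.0224	0.007385	0.0224	0.0224	0.007385	0.0224	0.007385	0.0224	0.0224	0.007035	0.0224	0.007385	0.007235	0.007255	0.0224	0.007084	0.007089	0.0224	0.0224	0.007385	0.007255	0.0224
F	0.012694	0.0385	0.0385	0.012694	0.0385	0.0385	0.012694	0.0385	0.012694	0.0385	0.0385	0.012092	0.0385	0.012694	0.012435	0.01247	0.0385	0.012176	0.012184	0.0385	0.0385	0.012694	0.01247	0.0385
P	0.017145	0.052	0.052	0.017145	0.052	0.052	0.017145	0.052	0.017145	0.052	0.052	0.016332	0.052	0.017145	0.016796	0.016843	0.052	0.016445	0.7	0.052	0.052	0.017145	0.016843	0.052
S	0.023475	0.0712	0.0712	0.023475	0.0712	0.0712	0.023475	0.0712	0.023475	0.0712	0.0712	0.022362	0.0712	0.023475	0.7	0.023062	0.0712	0.022517	0.022532	0.0712	0.0712	0.023475	0.023062	0.0712
T	0.019255	0.0584	0.0584	0.019255	0.0584	0.0584	0.019255	0.0584	0.019255	0.0584	0.0584	0.018342	0.0584	0.019255	0.018863	0.018916	0.0584	0.018469	0.018481	0.0584	0.0584	0.019255	0.018916	0.0584
W	0.004352	0.0132	0.0132	0.004352	0.0132	0.0132	0.004352	0.0132	0.004352	0.0132	0.0132	0.004146	0.0132	0.004352	0.004264	0.004276	0.0132	0.004175	0.004177	0.0132	0.0132	0.004352	0.004276	0.0132
Y	0.010584	0.0321	0.0321	0.010584	0.0321	0.0321	0.010584	0.0321	0.010584	0.0321	0.0321	0.010082	0.0321	0.010584	0.010368	0.010397	0.0321	0.010152	0.010158	0.0321	0.0321	0.010584	0.010397	0.0321
V	0.02153	0.0653	0.0653	0.02153	0.0653	0.0653	0.02153	0.0653	0.02153	0.0653	0.0653	0.020509	0.0653	0.02153	0.021092	0.021151	0.0653	0.020651	0.020665	0.0653	0.0653	0.02153	0.021151	0.0653
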