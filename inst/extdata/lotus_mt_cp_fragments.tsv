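no	length	start	end	genes_contained
1	1998	469237	471234	petN;psbM
2	1387	523411	524797	ycf3
3	1229	516533	517761	petL-petG-trnW(CCA)-trnP(UGG)
4	997	451200	452196	psbC
5	621	471275	471895	trnD(GTC)
6	321	230963	231283	psbC
7	297	452532	452828	psbD;psbC
8	211	181488	181698	ndhD
9	206	29058	29263	ycf2
10	206	318795	319000	ycf2
11	145	523258	523402	ycf3
12	141	472035	472175	trnT(GGT)
13	87	285719	285805	ycf2
14	84	426801	426884	trnN(GTT)
15	81	505480	505560	trnH(GTG)
16	78	123420	123497	trnM(CAT)
17	57	413440	413496	ndhE
18	56	91514	91569	trnT(GGT)
19	54	342137	342190	trnA(TGC)
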