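chrom	arm	start	end
1	1p	0	123400000
1	1q	123400000	248956422
2	2p	0	93900000
2	2q	93900000	242193529
3	3p	0	90900000
3	3q	90900000	198295559
4	4p	0	50000000
4	4q	50000000	190214555
5	5p	0	48800000
5	5q	48800000	181538259
6	6p	0	59800000
6	6q	59800000	170805979
7	7p	0	60100000
7	7q	60100000	159345973
8	8p	0	45200000
8	8q	45200000	145138636
9	9p	0	43000000
9	9q	43000000	138394717
10	10p	0	39800000
10	10q	39800000	133797422
11	11p	0	53400000
11	11q	53400000	135086622
12	12p	0	35500000
12	12q	35500000	133275309
13	13p	0	17700000
13	13q	17700000	114364328
14	14p	0	17200000
14	14q	17200000	107043718
15	15p	0	19000000
15	15q	19000000	101991189
16	16p	0	36800000
16	16q	36800000	90338345
17	17p	0	25100000
17	17q	25100000	83257441
18	18p	0	18500000
18	18q	18500000	80373285
19	19p	0	26200000
19	19q	26200000	58617616
20	20p	0	28100000
20	20q	28100000	64444167
21	21p	0	12000000
21	21q	12000000	46709983
22	22p	0	15000000
22	22q	15000000	50818468
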