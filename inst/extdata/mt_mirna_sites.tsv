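mirna	organism	start	end
hsa-miR-mit-1	human	6715	6735
hsa-miR-mit-2	human	8454	8472
hsa-miR-mit-3	human	9186	9207
hsa-miR-mit-4	human	10832	10851
hsa-miR-mit-5	human	5094	5115
hsa-miR-mit-6	human	2406	2426
hsa-miR-mit-1	chimp	6180	6200
hsa-miR-mit-2	chimp	7878	7896
hsa-miR-mit-3	chimp	8603	8624
hsa-miR-mit-4	chimp	10249	10268
hsa-miR-mit-5	chimp	4511	4532
hsa-miR-mit-6	chimp	1823	1843
hsa-miR-mit-1	orangutan	6152	6172
hsa-miR-mit-2	orangutan	-	-
hsa-miR-mit-3	orangutan	8641	8662
hsa-miR-mit-4	orangutan	-	-
hsa-miR-mit-5	orangutan	-	-
hsa-miR-mit-6	orangutan	-	-
hsa-miR-mit-1	mouse	-	-
hsa-miR-mit-2	mouse	-	-
hsa-miR-mit-3	mouse	-	-
hsa-miR-mit-4	mouse	-	-
hsa-miR-mit-5	mouse	-	-
hsa-miR-mit-6	mouse	1935	1955
hsa-miR-mit-1	rat	-	-
hsa-miR-mit-2	rat	-	-
hsa-miR-mit-3	rat	-	-
hsa-miR-mit-4	rat	-	-
hsa-miR-mit-5	rat	-	-
hsa-miR-mit-6	rat	1920	1940
hsa-miR-mit-1	rhesus	-	-
hsa-miR-mit-2	rhesus	-	-
hsa-miR-mit-3	rhesus	-	-
hsa-miR-mit-4	rhesus	-	-
hsa-miR-mit-5	rhesus	-	-
hsa-miR-mit-6	rhesus	-	-
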