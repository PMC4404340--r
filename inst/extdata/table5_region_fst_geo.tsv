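Asia_South	0	1855	3555	8951	5818	8124	7292	16559	16135
Asia_Southeast	0.1040	0	2352	10637	7071	6269	5498	18085	17245
Asia_East	0.0363	0.0351	0	12415	9294	5509	4201	19303	15386
Africa_Benin	0.5006	0.4033	0.4719	0	4127	16025	16049	7608	9501
Africa_Kenya	0.7226	0.6154	0.7044	0.1677	0	11913	12044	11017	13616
Oceania_Australia	0.2525	0.4524	0.2892	0.3094	0.5056	0	1611	14964	14468
Oceania_PNG	0.9430	0.9629	0.9536	0.9370	0.9664	0.5915	0	16115	14373
LatinAmerica_Others	0.9578	0.9472	0.9608	0.9402	0.9690	0.6203	0.8946	0	3971
LatinAmerica_CostaRica	0.9543	0.9467	0.9564	0.9446	0.9641	0.7755	0.9478	0.0373	0
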