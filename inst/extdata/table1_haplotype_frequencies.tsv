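haplotype	frequency
H1	1
H2	2
H3	1
H4	1
H5	1
H6	2
H7	1
H8	225
H9	2
H10	1
H11	1
H12	1
H13	1
H14	1
H15	1
H16	1
H17	1
H18	3
H19	1
H20	1
H21	2
H22	2
H23	32
H24	1
H25	1
H26	1
H27	1
H28	1
H29	1
H30	15
H31	2
H32	1
H33	2
H34	4
H35	143
H36	1
H37	2
H38	2
H39	29
H40	6
H41	1
H42	1
H43	1
H44	1
H45	1
H46	20
H47	1
H48	2
H49	2
H50	1
H51	1
H52	1
H53	1
H54	143
H55	1
H56	1
H57	1
H58	2
H59	1
H60	1
H61	1
H62	1
H63	1
H64	1
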