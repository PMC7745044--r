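channel	roi
ch11	left_PFC
ch12	left_PFC
ch13	left_PFC
ch14	left_PFC
ch15	left_PFC
ch16	left_PFC
ch17	right_PFC
ch18	right_PFC
ch19	right_PFC
ch20	right_PFC
ch21	right_PFC
ch22	left_PFC
ch23	left_PFC
ch24	left_PFC
ch25	left_PFC
ch26	left_PFC
ch27	right_PFC
ch28	right_PFC
ch29	right_PFC
ch30	right_PFC
ch31	right_PFC
ch32	left_PFC
ch33	left_PFC
ch34	left_PFC
ch35	left_PFC
ch36	left_PFC
ch37	right_PFC
ch38	right_PFC
ch39	right_PFC
ch40	right_PFC
ch41	right_PFC
ch42	right_PFC
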