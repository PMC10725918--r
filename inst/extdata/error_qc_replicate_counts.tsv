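locus	n_reactions	n_errors
DCA09	59	3
UDO43	59	2
DCA16	59	1
DCA18	60	2
DCA14	60	0
IAS-oli23	60	0
DCA03	60	1
GAPU71B	54	1
DCA05	60	0
DCA13	59	0
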