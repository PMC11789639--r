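gene	xi_expression
DDX3Y	1
UTY	1
ZFY	1
USP9Y	1
EIF1AY	1
KDM5D	1
TXLNGY	1
RPS4Y1	1
PRKY	1
NLGN4Y	1
SRY	0
RBMY	0
HSFY1	0
TSPY1	0
AMELY	0
TBL1Y	0
TMSB4Y	0
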