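gene	species	present
DDX3Y	opossum	0
DDX3Y	wallaby	0
DDX3Y	armadillo	1
DDX3Y	elephant	1
DDX3Y	cat	1
DDX3Y	dog	1
DDX3Y	horse	1
DDX3Y	bull	1
DDX3Y	mouse	1
DDX3Y	rat	1
DDX3Y	marmoset	1
DDX3Y	rhesus	1
DDX3Y	chimp	1
DDX3Y	human	1
UTY	opossum	0
UTY	wallaby	0
UTY	armadillo	1
UTY	elephant	1
UTY	cat	1
UTY	dog	1
UTY	horse	1
UTY	bull	1
UTY	mouse	1
UTY	rat	1
UTY	marmoset	1
UTY	rhesus	1
UTY	chimp	1
UTY	human	1
ZFY	opossum	0
ZFY	wallaby	0
ZFY	armadillo	1
ZFY	elephant	1
ZFY	cat	1
ZFY	dog	1
ZFY	horse	1
ZFY	bull	1
ZFY	mouse	1
ZFY	rat	1
ZFY	marmoset	1
ZFY	rhesus	1
ZFY	chimp	1
ZFY	human	1
USP9Y	opossum	0
USP9Y	wallaby	0
USP9Y	armadillo	1
USP9Y	elephant	1
USP9Y	cat	0
USP9Y	dog	1
USP9Y	horse	1
USP9Y	bull	1
USP9Y	mouse	1
USP9Y	rat	1
USP9Y	marmoset	1
USP9Y	rhesus	1
USP9Y	chimp	1
USP9Y	human	1
EIF1AY	opossum	0
EIF1AY	wallaby	0
EIF1AY	armadillo	1
EIF1AY	elephant	1
EIF1AY	cat	1
EIF1AY	dog	1
EIF1AY	horse	1
EIF1AY	bull	1
EIF1AY	mouse	0
EIF1AY	rat	0
EIF1AY	marmoset	1
EIF1AY	rhesus	1
EIF1AY	chimp	1
EIF1AY	human	1
KDM5D	opossum	0
KDM5D	wallaby	0
KDM5D	armadillo	1
KDM5D	elephant	1
KDM5D	cat	1
KDM5D	dog	1
KDM5D	horse	0
KDM5D	bull	0
KDM5D	mouse	1
KDM5D	rat	1
KDM5D	marmoset	1
KDM5D	rhesus	1
KDM5D	chimp	1
KDM5D	human	1
TXLNGY	opossum	0
TXLNGY	wallaby	0
TXLNGY	armadillo	1
TXLNGY	elephant	1
TXLNGY	cat	0
TXLNGY	dog	0
TXLNGY	horse	1
TXLNGY	bull	1
TXLNGY	mouse	0
TXLNGY	rat	0
TXLNGY	marmoset	1
TXLNGY	rhesus	1
TXLNGY	chimp	1
TXLNGY	human	1
RPS4Y1	opossum	0
RPS4Y1	wallaby	0
RPS4Y1	armadillo	1
RPS4Y1	elephant	0
RPS4Y1	cat	0
RPS4Y1	dog	0
RPS4Y1	horse	0
RPS4Y1	bull	0
RPS4Y1	mouse	0
RPS4Y1	rat	0
RPS4Y1	marmoset	1
RPS4Y1	rhesus	1
RPS4Y1	chimp	1
RPS4Y1	human	1
PRKY	opossum	0
PRKY	wallaby	0
PRKY	armadillo	0
PRKY	elephant	0
PRKY	cat	0
PRKY	dog	0
PRKY	horse	0
PRKY	bull	0
PRKY	mouse	1
PRKY	rat	0
PRKY	marmoset	1
PRKY	rhesus	1
PRKY	chimp	1
PRKY	human	1
NLGN4Y	opossum	0
NLGN4Y	wallaby	0
NLGN4Y	armadillo	0
NLGN4Y	elephant	0
NLGN4Y	cat	0
NLGN4Y	dog	0
NLGN4Y	horse	0
NLGN4Y	bull	0
NLGN4Y	mouse	0
NLGN4Y	rat	0
NLGN4Y	marmoset	1
NLGN4Y	rhesus	1
NLGN4Y	chimp	1
NLGN4Y	human	1
SRY	opossum	1
SRY	wallaby	1
SRY	armadillo	1
SRY	elephant	1
SRY	cat	1
SRY	dog	1
SRY	horse	1
SRY	bull	1
SRY	mouse	1
SRY	rat	1
SRY	marmoset	1
SRY	rhesus	1
SRY	chimp	1
SRY	human	1
RBMY	opossum	1
RBMY	wallaby	1
RBMY	armadillo	1
RBMY	elephant	1
RBMY	cat	1
RBMY	dog	1
RBMY	horse	1
RBMY	bull	1
RBMY	mouse	0
RBMY	rat	1
RBMY	marmoset	1
RBMY	rhesus	1
RBMY	chimp	1
RBMY	human	1
HSFY1	opossum	1
HSFY1	wallaby	1
HSFY1	armadillo	1
HSFY1	elephant	1
HSFY1	cat	1
HSFY1	dog	1
HSFY1	horse	1
HSFY1	bull	1
HSFY1	mouse	0
HSFY1	rat	0
HSFY1	marmoset	1
HSFY1	rhesus	1
HSFY1	chimp	1
HSFY1	human	1
TSPY1	opossum	1
TSPY1	wallaby	1
TSPY1	armadillo	1
TSPY1	elephant	1
TSPY1	cat	0
TSPY1	dog	0
TSPY1	horse	1
TSPY1	bull	1
TSPY1	mouse	1
TSPY1	rat	1
TSPY1	marmoset	1
TSPY1	rhesus	1
TSPY1	chimp	1
TSPY1	human	1
AMELY	opossum	1
AMELY	wallaby	1
AMELY	armadillo	1
AMELY	elephant	1
AMELY	cat	0
AMELY	dog	1
AMELY	horse	1
AMELY	bull	1
AMELY	mouse	0
AMELY	rat	0
AMELY	marmoset	1
AMELY	rhesus	1
AMELY	chimp	1
AMELY	human	1
TBL1Y	opossum	1
TBL1Y	wallaby	1
TBL1Y	armadillo	1
TBL1Y	elephant	1
TBL1Y	cat	1
TBL1Y	dog	1
TBL1Y	horse	1
TBL1Y	bull	1
TBL1Y	mouse	0
TBL1Y	rat	0
TBL1Y	marmoset	0
TBL1Y	rhesus	0
TBL1Y	chimp	0
TBL1Y	human	0
TMSB4Y	opossum	1
TMSB4Y	wallaby	1
TMSB4Y	armadillo	0
TMSB4Y	elephant	0
TMSB4Y	cat	0
TMSB4Y	dog	0
TMSB4Y	horse	0
TMSB4Y	bull	0
TMSB4Y	mouse	0
TMSB4Y	rat	0
TMSB4Y	marmoset	0
TMSB4Y	rhesus	1
TMSB4Y	chimp	1
TMSB4Y	human	1
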