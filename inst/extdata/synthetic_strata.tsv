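gene	species
DDX3Y	armadillo
DDX3Y	elephant
DDX3Y	cat
DDX3Y	dog
DDX3Y	horse
DDX3Y	bull
DDX3Y	mouse
DDX3Y	rat
DDX3Y	marmoset
DDX3Y	rhesus
DDX3Y	chimp
DDX3Y	human
UTY	armadillo
UTY	elephant
UTY	cat
UTY	dog
UTY	horse
UTY	bull
UTY	mouse
UTY	rat
UTY	marmoset
UTY	rhesus
UTY	chimp
UTY	human
ZFY	armadillo
ZFY	elephant
ZFY	cat
ZFY	dog
ZFY	horse
ZFY	bull
ZFY	mouse
ZFY	rat
ZFY	marmoset
ZFY	rhesus
ZFY	chimp
ZFY	human
USP9Y	armadillo
USP9Y	elephant
USP9Y	cat
USP9Y	dog
USP9Y	horse
USP9Y	bull
USP9Y	mouse
USP9Y	rat
USP9Y	marmoset
USP9Y	rhesus
USP9Y	chimp
USP9Y	human
EIF1AY	armadillo
EIF1AY	elephant
EIF1AY	cat
EIF1AY	dog
EIF1AY	horse
EIF1AY	bull
EIF1AY	mouse
EIF1AY	rat
EIF1AY	marmoset
EIF1AY	rhesus
EIF1AY	chimp
EIF1AY	human
KDM5D	armadillo
KDM5D	elephant
KDM5D	cat
KDM5D	dog
KDM5D	horse
KDM5D	bull
KDM5D	mouse
KDM5D	rat
KDM5D	marmoset
KDM5D	rhesus
KDM5D	chimp
KDM5D	human
TXLNGY	armadillo
TXLNGY	elephant
TXLNGY	cat
TXLNGY	dog
TXLNGY	horse
TXLNGY	bull
TXLNGY	mouse
TXLNGY	rat
TXLNGY	marmoset
TXLNGY	rhesus
TXLNGY	chimp
TXLNGY	human
RPS4Y1	armadillo
RPS4Y1	elephant
RPS4Y1	cat
RPS4Y1	dog
RPS4Y1	horse
RPS4Y1	bull
RPS4Y1	mouse
RPS4Y1	rat
RPS4Y1	marmoset
RPS4Y1	rhesus
RPS4Y1	chimp
RPS4Y1	human
PRKY	mouse
PRKY	rat
PRKY	marmoset
PRKY	rhesus
PRKY	chimp
PRKY	human
NLGN4Y	marmoset
NLGN4Y	rhesus
NLGN4Y	chimp
NLGN4Y	human
SRY	opossum
SRY	wallaby
SRY	armadillo
SRY	elephant
SRY	cat
SRY	dog
SRY	horse
SRY	bull
SRY	mouse
SRY	rat
SRY	marmoset
SRY	rhesus
SRY	chimp
SRY	human
RBMY	opossum
RBMY	wallaby
RBMY	armadillo
RBMY	elephant
RBMY	cat
RBMY	dog
RBMY	horse
RBMY	bull
RBMY	mouse
RBMY	rat
RBMY	marmoset
RBMY	rhesus
RBMY	chimp
RBMY	human
HSFY1	opossum
HSFY1	wallaby
HSFY1	armadillo
HSFY1	elephant
HSFY1	cat
HSFY1	dog
HSFY1	horse
HSFY1	bull
HSFY1	mouse
HSFY1	rat
HSFY1	marmoset
HSFY1	rhesus
HSFY1	chimp
HSFY1	human
TSPY1	opossum
TSPY1	wallaby
TSPY1	armadillo
TSPY1	elephant
TSPY1	cat
TSPY1	dog
TSPY1	horse
TSPY1	bull
TSPY1	mouse
TSPY1	rat
TSPY1	marmoset
TSPY1	rhesus
TSPY1	chimp
TSPY1	human
AMELY	opossum
AMELY	wallaby
AMELY	armadillo
AMELY	elephant
AMELY	cat
AMELY	dog
AMELY	horse
AMELY	bull
AMELY	mouse
AMELY	rat
AMELY	marmoset
AMELY	rhesus
AMELY	chimp
AMELY	human
TBL1Y	opossum
TBL1Y	wallaby
TBL1Y	armadillo
TBL1Y	elephant
TBL1Y	cat
TBL1Y	dog
TBL1Y	horse
TBL1Y	bull
TBL1Y	mouse
TBL1Y	rat
TBL1Y	marmoset
TBL1Y	rhesus
TBL1Y	chimp
TBL1Y	human
TMSB4Y	opossum
TMSB4Y	wallaby
TMSB4Y	armadillo
TMSB4Y	elephant
TMSB4Y	cat
TMSB4Y	dog
TMSB4Y	horse
TMSB4Y	bull
TMSB4Y	mouse
TMSB4Y	rat
TMSB4Y	marmoset
TMSB4Y	rhesus
TMSB4Y	chimp
TMSB4Y	human
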