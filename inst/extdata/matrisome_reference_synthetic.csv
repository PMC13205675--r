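identifier,division,category
col1a1,core matrisome,collagens
col1a2,core matrisome,collagens
col3a1,core matrisome,collagens
col4a1,core matrisome,collagens
col6a1,core matrisome,collagens
acan,core matrisome,proteoglycans
bgn,core matrisome,proteoglycans
dcn,core matrisome,proteoglycans
hspg2,core matrisome,proteoglycans
vcan,core matrisome,proteoglycans
fn1,core matrisome,glycoproteins
lamb1,core matrisome,glycoproteins
thbs4,core matrisome,glycoproteins
tnc,core matrisome,glycoproteins
nid1,core matrisome,glycoproteins
mmp2,matrisome-associated,ECM regulators
mmp9,matrisome-associated,ECM regulators
timp1,matrisome-associated,ECM regulators
loxl2,matrisome-associated,ECM regulators
adamts1,matrisome-associated,ECM regulators
anxa2,matrisome-associated,ECM-affiliated
lgals1,matrisome-associated,ECM-affiliated
c1qa,matrisome-associated,ECM-affiliated
plod1,matrisome-associated,ECM-affiliated
sdc1,matrisome-associated,ECM-affiliated
ctgf,matrisome-associated,secreted factors
s100a8,matrisome-associated,secreted factors
wnt4,matrisome-associated,secreted factors
tgfb1,matrisome-associated,secreted factors
igf1,matrisome-associated,secreted factors
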