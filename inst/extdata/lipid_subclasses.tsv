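subclass	lipid_class	expected_chains	headgroup_volume	sphingo	fixed_volume	description
PC	glycerophospholipid	2	320	0	NA	phosphatidylcholine
PE	glycerophospholipid	2	250	0	NA	phosphatidylethanolamine
PI	glycerophospholipid	2	350	0	NA	phosphatidylinositol
PS	glycerophospholipid	2	290	0	NA	phosphatidylserine
PA	glycerophospholipid	2	170	0	NA	phosphatidic acid
PG	glycerophospholipid	2	260	0	NA	phosphatidylglycerol
PGP	glycerophospholipid	2	320	0	NA	phosphatidylglycerol-phosphate
BMP	glycerophospholipid	2	330	0	NA	bis(monoacylglycero)phosphate
CL	glycerophospholipid	4	530	0	NA	cardiolipin
LPC	glycerophospholipid	1	290	0	NA	lyso-phosphatidylcholine
LPE	glycerophospholipid	1	220	0	NA	lyso-phosphatidylethanolamine
LPG	glycerophospholipid	1	230	0	NA	lyso-phosphatidylglycerol
LPA	glycerophospholipid	1	140	0	NA	lyso-phosphatidic acid
LPI	glycerophospholipid	1	320	0	NA	lyso-phosphatidylinositol
LPS	glycerophospholipid	1	260	0	NA	lyso-phosphatidylserine
SM	sphingolipid	2	250	1	NA	sphingomyelin
Cer	sphingolipid	2	80	1	NA	ceramide
CerP	sphingolipid	2	140	1	NA	ceramide 1-phosphate
HexCer	sphingolipid	2	240	1	NA	hexosylceramide
Hex2Cer	sphingolipid	2	400	1	NA	dihexosylceramide
SHexCer	sphingolipid	2	290	1	NA	sulfated hexosylceramide
TAG	glycerolipid	3	90	0	NA	triacylglycerol
DAG	glycerolipid	2	95	0	NA	diacylglycerol
MAG	glycerolipid	1	100	0	NA	monoacylglycerol
FA	other	1	35	0	NA	fatty acid
FAL	other	1	30	0	NA	fatty acid aldehyde or alcohol
VA	other	0	NA	0	290	vitamin A (retinol), fixed whole-molecule volume
ST	sterol	0	NA	0	630	sterol, fixed whole-molecule volume
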