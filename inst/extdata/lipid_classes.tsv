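lipid_class	category	n_chains	ether
CE	sterols	1	FALSE
Cer	sphingolipids	2	FALSE
HexCer	sphingolipids	2	FALSE
SM	sphingolipids	2	FALSE
DAG	glycerolipids	2	FALSE
TAG	glycerolipids	3	FALSE
CL	glycerophospholipids	4	FALSE
PA	glycerophospholipids	2	FALSE
PC	glycerophospholipids	2	FALSE
PE	glycerophospholipids	2	FALSE
PG	glycerophospholipids	2	FALSE
PI	glycerophospholipids	2	FALSE
PS	glycerophospholipids	2	FALSE
PC O-	glycerophospholipids	2	TRUE
PE O-	glycerophospholipids	2	TRUE
LPA	glycerophospholipid intermediates	1	FALSE
LPC	glycerophospholipid intermediates	1	FALSE
LPE	glycerophospholipid intermediates	1	FALSE
LPG	glycerophospholipid intermediates	1	FALSE
LPI	glycerophospholipid intermediates	1	FALSE
LPS	glycerophospholipid intermediates	1	FALSE
LPC O-	glycerophospholipid intermediates	1	TRUE
LPE O-	glycerophospholipid intermediates	1	TRUE
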