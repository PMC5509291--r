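gene_id	imprinting_status
SLC22A18	maternal
PEG10	paternal
MEST	paternal
NAPIL5	paternal
MIMT1	paternal
PSIMCT-1	paternal
PEG3	paternal
LIN28B	paternal
DGCR6	unknown
PLAGL1	paternal
ANO1	maternal
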