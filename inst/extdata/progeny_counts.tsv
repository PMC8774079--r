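line_id	parent_genotype	genotype	count	source
ShS5-SLF5_line2	S3,S3L	S3/S3L	12	reported
ShS5-SLF5_line2	S3,S3L	S3L/S3L	9	reported
ShS5-SLF5_line2	S3,S3L	S3/S3	0	reported
ShS5-SLF5_line5	S3,S3L	S3/S3L	14	reported
ShS5-SLF5_line5	S3,S3L	S3L/S3L	9	reported
ShS5-SLF5_line5	S3,S3L	S3/S3	0	reported
ShS5-SLF6_line1	S3,S3L	S3/S3	11	reported
ShS5-SLF6_line1	S3,S3L	S3/S3L	12	reported
ShS5-SLF6_line1	S3,S3L	S3L/S3L	0	reported
ShS5-SLF6_line3	S3,S3L	S3/S3	13	reported
ShS5-SLF6_line3	S3,S3L	S3/S3L	10	reported
ShS5-SLF6_line3	S3,S3L	S3L/S3L	0	reported
AhSLF1_line1	S3,S3L	S3/S3	6	synthetic
AhSLF1_line1	S3,S3L	S3/S3L	11	synthetic
AhSLF1_line1	S3,S3L	S3L/S3L	5	synthetic
AhSLF2_line1	S3,S3L	S3/S3	5	synthetic
AhSLF2_line1	S3,S3L	S3/S3L	12	synthetic
AhSLF2_line1	S3,S3L	S3L/S3L	6	synthetic
AhSLF3_line1	S3,S3L	S3/S3	7	synthetic
AhSLF3_line1	S3,S3L	S3/S3L	10	synthetic
AhSLF3_line1	S3,S3L	S3L/S3L	4	synthetic
AmChr7-SLFL1_line1	S3,S3L	S3/S3	0	synthetic
AmChr7-SLFL1_line1	S3,S3L	S3/S3L	10	synthetic
AmChr7-SLFL1_line1	S3,S3L	S3L/S3L	11	synthetic
PaS4-SLFL1_line1	S3,S3L	S3/S3	5	synthetic
PaS4-SLFL1_line1	S3,S3L	S3/S3L	10	synthetic
PaS4-SLFL1_line1	S3,S3L	S3L/S3L	6	synthetic
PaS4-SLFL2_line1	S3,S3L	S3/S3	6	synthetic
PaS4-SLFL2_line1	S3,S3L	S3/S3L	9	synthetic
PaS4-SLFL2_line1	S3,S3L	S3L/S3L	5	synthetic
PaSFB1_line1	S3,S3L	S3/S3	4	synthetic
PaSFB1_line1	S3,S3L	S3/S3L	11	synthetic
PaSFB1_line1	S3,S3L	S3L/S3L	6	synthetic
PaSFB4_line1	S3,S3L	S3/S3	5	synthetic
PaSFB4_line1	S3,S3L	S3/S3L	13	synthetic
PaSFB4_line1	S3,S3L	S3L/S3L	5	synthetic
MdSFBBb-S9_line1	S3,S3L	S3/S3	6	synthetic
MdSFBBb-S9_line1	S3,S3L	S3/S3L	10	synthetic
MdSFBBb-S9_line1	S3,S3L	S3L/S3L	6	synthetic
AcSc4SLF4_line1	S3,S3L	S3/S3	12	synthetic
AcSc4SLF4_line1	S3,S3L	S3/S3L	9	synthetic
AcSc4SLF4_line1	S3,S3L	S3L/S3L	0	synthetic
AcSc4SLF5_line1	S3,S3L	S3/S3	5	synthetic
AcSc4SLF5_line1	S3,S3L	S3/S3L	11	synthetic
AcSc4SLF5_line1	S3,S3L	S3L/S3L	5	synthetic
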