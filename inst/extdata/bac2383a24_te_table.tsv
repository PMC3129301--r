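# TE/gene accounting of wheat BAC clone 2383A24 (total length 113605 bp)
# columns: name, category path, copy number, total length in bp
name	category	copies	length_bp
RLG_Egug_2383A24_solo_LTR	class_I/LTR/gypsy	1	1503
RLG_Wilma_2383A24_solo_LTR	class_I/LTR/gypsy	1	1490
RLG_Sabrina_2383A24-1p	class_I/LTR/gypsy	1	1505
RLG_Fatima_2383A24-1p_2_3	class_I/LTR/gypsy	3	27210
RLC_WIS_2383A24-1	class_I/LTR/copia	1	8353
RLC_Barbara_2383A24-1p	class_I/LTR/copia	1	6384
RLC_Claudia_2383A24-1p	class_I/LTR/copia	1	9579
RLX_Xalax_2383A24-1p	class_I/LTR/unknown	1	1566
RIX_2383A24-1p	class_I/non-LTR	1	1014
DTC_Caspar_2383A24-1p	class_II/CACTA	1	3693
MITE_2383A24	MITE	6	747
Spelt1_2383A24-1	tandem_repeat	1	177
Spelt1_2383A24-2	tandem_repeat	1	177
Spelt1_2383A24-3	tandem_repeat	1	177
Spelt1_2383A24-4	tandem_repeat	1	177
Spelt1_2383A24-5	tandem_repeat	1	177
Spelt1_2383A24-6t	tandem_repeat	1	125
genes_2383A24	gene	5	4913
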