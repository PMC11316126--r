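# lookup_version: 1.0
# Descriptor -> topology-class table for steric-zipper interfaces.
# sheet_sense: parallel / antiparallel beta-sheets
# surface_parity: same  = like surfaces meet (face-to-face or back-to-back)
#                 opposite = unlike surfaces meet (face-to-back)
# sheet_direction: same = N-to-N / up-up; opposite = N-to-C / up-down
# extra_symmetry_flag: reserved for the two additional parallel classes
#   (9, 10) for which no operational geometric criterion is published;
#   they are deliberately left untranscribed and are never emitted.
sheet_sense	surface_parity	sheet_direction	extra_symmetry_flag	class_id
parallel	same	opposite	none	1
parallel	opposite	same	none	2
parallel	same	same	none	3
parallel	opposite	opposite	none	4
antiparallel	same	same	none	5
antiparallel	same	opposite	none	6
antiparallel	opposite	same	none	7
antiparallel	opposite	opposite	none	8
parallel	NA	NA	untranscribed	9
parallel	NA	NA	untranscribed	10
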