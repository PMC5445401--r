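cell_line	domes_observed	domes_per_field	domes_per_21_fields
MT3	yes/no	0.1	2.1
MT3dCT	yes	2.72	57.22
MT3dNT	no	0	0
MT1E	no	0	0
MT1E-CT	yes	2.69	56.44
MT1E-NT	no	0	0
parent	no	0	0
blank_vector	no	0	0
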