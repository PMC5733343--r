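# Degradation route of salicylic alcohol derivatives.
# record	name/from	peak_id/to	formula/type	expected_undetectable
node	salicortin	40	C20H24O10	FALSE
node	acetylsalicin	23	C15H20O8	FALSE
node	tremulacin	58	C27H28O11	FALSE
node	salicin	10	C13H18O7	FALSE
node	saligenin	12	C7H8O2	FALSE
node	salicylic acid	38	C7H6O3	FALSE
node	gentisic acid	14	C7H6O4	FALSE
edge	salicortin	salicin	HYDROLYSIS
edge	acetylsalicin	salicin	HYDROLYSIS
edge	tremulacin	salicin	HYDROLYSIS
edge	salicin	saligenin	DEGLYCOSYLATION
edge	saligenin	salicylic acid	OXIDATION
edge	salicylic acid	gentisic acid	OXIDATION
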