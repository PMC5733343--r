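# Microbial degradation route of naringenin glycosides.
# record	name/from	peak_id/to	formula/type	expected_undetectable
node	naringenin-7-glucoside	47	C21H22O10	FALSE
node	(+)-naringenin-5-glucoside	37	C21H22O10	FALSE
node	(-)-naringenin-5-glucoside	41	C21H22O10	FALSE
node	naringenin	56	C15H12O5	FALSE
node	3-(4-hydroxyphenyl)propionic acid	NA	C9H10O3	TRUE
node	phloroglucinol	NA	C6H6O3	TRUE
node	phenylpropionic acid	49	C9H10O2	FALSE
node	4-hydroxybenzoic acid	15	C7H6O3	FALSE
edge	naringenin-7-glucoside	naringenin	DEGLYCOSYLATION
edge	(+)-naringenin-5-glucoside	naringenin	DEGLYCOSYLATION
edge	(-)-naringenin-5-glucoside	naringenin	DEGLYCOSYLATION
edge	naringenin	3-(4-hydroxyphenyl)propionic acid	C_RING_CLEAVAGE
edge	naringenin	phloroglucinol	C_RING_CLEAVAGE
edge	3-(4-hydroxyphenyl)propionic acid	phenylpropionic acid	DEHYDROXYLATION
edge	3-(4-hydroxyphenyl)propionic acid	4-hydroxybenzoic acid	ALPHA_OXIDATION
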