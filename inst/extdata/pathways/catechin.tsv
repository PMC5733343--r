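# Microbial degradation route of catechin / flavan-3-ols.
# record	name/from	peak_id/to	formula/type	expected_undetectable
node	catechin	19	C15H14O6	FALSE
node	(epi)gallocatechin	7	C15H14O7	FALSE
node	5-(3',4',5'-trihydroxyphenyl)-gamma-valerolactone	13	C11H12O5	FALSE
node	5-(dihydroxyphenyl)-gamma-valerolactone	28	C11H12O4	FALSE
node	4-hydroxy-5-(dihydroxyphenyl)valeric acid	16	C11H14O5	FALSE
node	4-oxo-5-(dihydroxyphenylvaleric)acid	20	C11H12O5	FALSE
node	5-(dihydroxyphenyl)valeric acid	42	C11H14O4	FALSE
node	4-hydroxy-5-(hydroxyphenyl)valeric acid	35	C11H14O4	FALSE
node	hydroxyphenylvaleric acid	54	C11H14O3	FALSE
node	dihydrocaffeic acid	17	C9H10O4	FALSE
node	3-(3-hydroxyphenyl)propionic acid	34	C9H10O3	FALSE
node	phenylpropionic acid	49	C9H10O2	FALSE
node	protocatechuic acid	6	C7H6O4	FALSE
edge	catechin	5-(dihydroxyphenyl)-gamma-valerolactone	C_RING_CLEAVAGE
edge	catechin	4-hydroxy-5-(dihydroxyphenyl)valeric acid	C_RING_CLEAVAGE
edge	(epi)gallocatechin	5-(3',4',5'-trihydroxyphenyl)-gamma-valerolactone	C_RING_CLEAVAGE
edge	5-(dihydroxyphenyl)-gamma-valerolactone	4-oxo-5-(dihydroxyphenylvaleric)acid	OXIDATION
edge	4-oxo-5-(dihydroxyphenylvaleric)acid	5-(dihydroxyphenyl)valeric acid	REDUCTION
edge	4-hydroxy-5-(dihydroxyphenyl)valeric acid	4-hydroxy-5-(hydroxyphenyl)valeric acid	DEHYDROXYLATION
edge	5-(dihydroxyphenyl)valeric acid	hydroxyphenylvaleric acid	DEHYDROXYLATION
edge	4-hydroxy-5-(hydroxyphenyl)valeric acid	hydroxyphenylvaleric acid	OTHER
edge	5-(dihydroxyphenyl)valeric acid	dihydrocaffeic acid	BETA_OXIDATION
edge	hydroxyphenylvaleric acid	3-(3-hydroxyphenyl)propionic acid	BETA_OXIDATION
edge	dihydrocaffeic acid	3-(3-hydroxyphenyl)propionic acid	DEHYDROXYLATION
edge	3-(3-hydroxyphenyl)propionic acid	phenylpropionic acid	DEHYDROXYLATION
edge	dihydrocaffeic acid	protocatechuic acid	OTHER
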