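accession	name	mw	pi	sequence
P09683	Secretin (mature chain)	3040.0	9.46	HSDGTFTSELSRLREGARLQRLLQGLV
P01308	Insulin	5807.6	5.39	
P01275	Glucagon	3482.7	6.75	HSQGTFTSDYSKYLDSRRAQDFVQWLMNT
P61278	Somatostatin-14	1637.9	9.90	AGCKNFFWKTFTSC
P01275-7	Glucagon-like peptide 1 (7-36 amide)	3297.7	5.53	
P09681	Gastric inhibitory polypeptide	4983.6	7.62	
P10082	Peptide YY	4310.5	6.72	
P01303	Neuropeptide Y	4271.7	7.00	
Q9UBU3	Ghrelin	3370.9	11.20	
P01350	Gastrin-17	2098.2	3.40	
P06307	Cholecystokinin-8	1143.3	3.95	
P01282	Vasoactive intestinal peptide	3325.8	9.90	HSDAVFTDNYTRLRKQMAVKKYLNSILN
P01258	Calcitonin	3454.9	8.70	CGNLSTCMLGTYTQDFNKFHTFPQTAIGVGAP
P01270	Parathyroid hormone (1-34)	4117.8	9.10	
P01189	Adrenocorticotropin (1-39)	4541.1	7.90	
P01178	Oxytocin	1007.2	8.60	CYIQNCPLG
P01185	Arginine vasopressin	1084.2	10.90	CYFQNCPRG
P01042	Bradykinin	1060.2	12.00	RPPGFSPFR
P20366	Substance P	1347.6	11.00	RPKPQQFFGLM
P01019	Angiotensin II	1046.2	7.60	DRVYIHPF
P05305	Endothelin-1	2491.9	4.50	
P10997	Islet amyloid polypeptide	3903.3	8.90	
P16860	Brain natriuretic peptide 32	3464.0	10.90	
P12872	Motilin	2698.9	8.40	FVPIFTYGELQRMQEKERNKGQ
P30990	Neurotensin	1672.9	9.50	
P22466	Galanin	3157.3	9.80	
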