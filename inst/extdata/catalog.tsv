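drug_id	description	dose_form	strength	active_ingredients	required	default_verb	default_dose	default_route	default_frequency	default_aux
D001	lisinopril 10 mg oral tablet	tablet	10 mg	lisinopril	verb;dose;route;frequency	take		by mouth		
D002	methotrexate 2.5 mg oral tablet	tablet	2.5 mg	methotrexate	verb;dose;route;frequency	take		by mouth		
D003	amoxicillin 500 mg oral capsule	capsule	500 mg	amoxicillin	verb;dose;route;frequency	take		by mouth		
D004	montelukast 4 mg chewable tablet	tablet	4 mg	montelukast	verb;dose;route;frequency	chew		by mouth		
D005	hydrocortisone 1% topical cream	cream	1%	hydrocortisone	verb;route;frequency	apply		topically		
D006	insulin glargine 100 units/ml pen-injector	pen-injector	100 units/ml	insulin glargine	verb;dose;route;frequency	inject		subcutaneously		
D007	albuterol 90 mcg inhalation aerosol	aerosol	90 mcg	albuterol	verb;dose;route;frequency	inhale		by inhalation		
D008	latanoprost 0.005% ophthalmic solution	solution	0.005%	latanoprost	verb;dose;route;frequency	instill				
D009	omeprazole 20 mg delayed-release capsule	capsule	20 mg	omeprazole	verb;dose;route;frequency	take		by mouth	once daily	
D010	ondansetron 4 mg oral tablet	tablet	4 mg	ondansetron	verb;dose;route;frequency	take		by mouth		for nausea
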