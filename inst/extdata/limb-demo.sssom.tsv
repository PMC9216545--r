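#curie_map:
#  FMA: http://purl.obolibrary.org/obo/FMA_
#  MA: http://purl.obolibrary.org/obo/MA_
#  orcid: https://orcid.org/
#  UBERON: http://purl.obolibrary.org/obo/UBERON_
#  UMLS: https://uts.nlm.nih.gov/uts/umls/concept/
#license: https://creativecommons.org/licenses/by/4.0/
#mapping_set_description: synthetic demonstration set for the anatomical limb cross-walk
#mapping_set_id: https://example.org/mappings/limb-demo
subject_id	subject_label	predicate_id	object_id	object_label	match_type	author_id	mapping_date
FMA:24875	Free limb	skos:exactMatch	UBERON:0002101	limb	HumanCurated	orcid:0000-0002-7356-1779	2021-10-01
UBERON:0002101	limb	skos:exactMatch	MA:0000007	limb	HumanCurated		
UBERON:0002101	limb	skos:relatedMatch	UMLS:C0015385	Extremities	HumanCurated		
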