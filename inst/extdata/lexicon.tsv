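concept_id	snomed_code	category	pattern	notes
tumor.mass	4147007	tumor_mass	mass(?:es)?	generic mass lexeme; recategorized to lymph_node when a nodal lexeme co-occurs in the sentence
tumor.tumor	108369006	tumor_mass	tumou?rs?
tumor.lesion	52988006	tumor_mass	lesions?
tumor.nodule	27925004	tumor_mass	nodules?	pulmonary nodule; distinct from lymph-node lexemes
tumor.neoplasm	108369006	tumor_mass	neoplasms?
tumor.opacity	263654008	tumor_mass	opacity|opacities|opacification
tumor.malignancy	363346000	tumor_mass	malignanc(?:y|ies)|cancer|carcinoma
node.lymph_node	59441001	lymph_node	lymph ?nodes?
node.node	59441001	lymph_node	nodes?	bare nodal lexeme
node.adenopathy	30746006	lymph_node	(?:lymph)?adenopathy
inv.main_bronchus	102297006	involvement_target	main ?stem bronchus|main bronchus|mainstem bronchus	T2 tier
inv.visceral_pleura	82094008	involvement_target	visceral pleura|pleura|pleural thickening	T2 tier
inv.chest_wall	78904004	involvement_target	chest wall|thoracic wall	T3 tier
inv.parietal_pericardium	76848001	involvement_target	(?:parietal )?pericardium|pericardial	T3 tier
inv.phrenic_nerve	50230006	involvement_target	phrenic nerve	T3 tier
inv.mediastinum	72410000	involvement_target	mediastinum	T4 tier; adjectival mediastinal deliberately not matched
inv.diaphragm	5798000	involvement_target	diaphragm	T4 tier
inv.heart	80891009	involvement_target	heart|cardiac chambers?	T4 tier
inv.great_vessels	59820001	involvement_target	great vessels?|aortic arch|aorta|pulmonary artery|superior vena cava	T4 tier
inv.trachea	44567001	involvement_target	trachea(?:l wall)?	T4 tier
inv.carina	28700002	involvement_target	carina	T4 tier
inv.esophagus	32849002	involvement_target	o?esophagus|o?esophageal wall	T4 tier
inv.recurrent_laryngeal_nerve	24727002	involvement_target	recurrent laryngeal nerve	T4 tier
inv.vertebral_body	51282000	involvement_target	vertebral bod(?:y|ies)|vertebra(?:e)?	T4 tier
pres.post_obstructive_atelectasis	46621007	presence_finding	post[- ]?obstructive atelectasis|obstructive atelectasis	T2 presence
pres.obstructive_pneumonitis	205237003	presence_finding	(?:post[- ]?obstructive |obstructive )pneumonitis	T2 presence
pres.atelectasis_generic	46621007	presence_finding	atelectasis	suppressed when a gravity-type adjective co-occurs in the sentence
pres.satellite	428481002	presence_finding	satellite (?:nodules?|lesions?)	T3 presence, same lobe
loc.rul	45653009	anatomic_location	right upper lobe|RUL
loc.rml	72481006	anatomic_location	right middle lobe|RML
loc.rll	266005	anatomic_location	right lower lobe|RLL
loc.lul	44714003	anatomic_location	left upper lobe|LUL
loc.lll	41224006	anatomic_location	left lower lobe|LLL
loc.lingula	79815007	anatomic_location	lingula(?:r segment)?
loc.right_lung	3341006	anatomic_location	right lung|right hemithorax
loc.left_lung	44029006	anatomic_location	left lung|left hemithorax
loc.hilar	53800008	anatomic_location	(?:peri)?hilar|hilum	nodal station
loc.subcarinal	228570002	anatomic_location	subcarinal	nodal station
loc.paratracheal	228567000	anatomic_location	paratracheal	nodal station
loc.supraclavicular	76838003	anatomic_location	supraclavicular	nodal station
loc.prevascular	228569001	anatomic_location	prevascular|precarinal	nodal station
bl.kidney	64033007	blacklist_term	kidneys?|renal
bl.liver	10200004	blacklist_term	liver|hepatic
bl.adrenal	23451007	blacklist_term	adrenal(?: gland)?s?
bl.thyroid	69748006	blacklist_term	thyroid
bl.cyst	441457006	blacklist_term	cysts?|cystic	documented trade-off: also suppresses cystic lung tumors
bl.spleen	78961009	blacklist_term	spleen|splenic
bl.pancreas	15776009	blacklist_term	pancreas|pancreatic
bl.bowel	71854001	blacklist_term	bowel|colon|gastric|stomach
bl.prostate	41216001	blacklist_term	prostate|prostatic
bl.breast	76752008	blacklist_term	breast
bl.ovary	15497006	blacklist_term	ovar(?:y|ies|ian)
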