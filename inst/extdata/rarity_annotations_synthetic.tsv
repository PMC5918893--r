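island	taxon_group	species	category	evidence
Madeira	spiders	Centromerus variegatus	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Ceratinopsis acripes	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Dipoenata longitarsis	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Dysdera diversa	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Frontiphantes fulgurenotatus	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Lepthyphantes impudicus	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Lepthyphantes mauli	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	spiders	Macaroeris n. sp.	true_rare	undescribed laurel-forest endemic, consistently scarce
Madeira	spiders	Meta stridulans	true_rare	ground-active laurel-forest endemic, consistently scarce
Madeira	ground_beetles	Bradycellus maderensis	true_rare	flightless forest endemic, consistently scarce
Madeira	ground_beetles	Trechus maderensis	true_rare	flightless forest endemic, consistently scarce
Madeira	ground_beetles	Trechus minyops	true_rare	flightless forest endemic, consistently scarce
Madeira	ground_beetles	Trechus nigrocruciatus	true_rare	flightless forest endemic, consistently scarce
Madeira	ground_beetles	Zargus schaumii	true_rare	flightless forest endemic, consistently scarce
Madeira	spiders	Diplostyla concolor	tourist	widespread synanthropic species, common outside the forest
Madeira	spiders	Ero aphana	tourist	widespread species, common in adjacent open habitats
Madeira	spiders	Microlinyphia johnsoni	tourist	common in adjacent open and edge habitats
Madeira	spiders	Poeciloneta variegata	tourist	widespread introduced species, common outside the forest
Madeira	spiders	Tetragnatha intermedia	tourist	riparian/edge species, marginal in the forest interior
Madeira	spiders	Enoplognatha sattleri	microhabitat_specialist	vegetation dweller, undersampled by ground-level traps
Madeira	spiders	Frontinellina dearmata	microhabitat_specialist	canopy/vegetation sheet-web builder, rarely at ground level
Madeira	spiders	Misumena spinifera	microhabitat_specialist	flower/foliage ambush hunter, rarely at ground level
Madeira	spiders	Paidiscura orotavensis	microhabitat_specialist	shrub-layer cobweb builder, undersampled by pitfall traps
Madeira	spiders	Philodromus insulanus	microhabitat_specialist	arboreal runner, rarely at ground level
Madeira	spiders	Steatoda nobilis	microhabitat_specialist	web builder on shrubs and structures, rarely at ground level
Madeira	spiders	Zygiella minima	microhabitat_specialist	orb-web builder on vegetation, rarely at ground level
Madeira	ground_beetles	Amara aenea	tourist	winged open-habitat species, common outside the forest
Madeira	ground_beetles	Harpalus attenuatus	tourist	winged open-habitat species, common outside the forest
Madeira	ground_beetles	Trechus fulvus	tourist	widespread species, marginal in the forest interior
Madeira	ground_beetles	Cymindis maderae	microhabitat_specialist	under bark and stones, seldom on the soil surface
Madeira	ground_beetles	Nesarpalus gregarius	microhabitat_specialist	deep litter/soil crevice dweller, undersampled by traps
Madeira	ground_beetles	Olisthopus ericae	microhabitat_specialist	under bark, seldom on the soil surface
Madeira	ground_beetles	Olisthopus maderensis	microhabitat_specialist	lives under tree bark, seldom found at the soil surface
Madeira	ground_beetles	Paradromius insularis	microhabitat_specialist	lives under tree bark, seldom found at the soil surface
Madeira	ground_beetles	Trechus custos	microhabitat_specialist	moss and dead-wood dweller, undersampled by traps
Terceira	spiders	Erigone atra	tourist	aeronaut coloniser, abundant in surrounding pastures
Terceira	spiders	Erigone autumnalis	tourist	aeronaut coloniser, abundant in surrounding pastures
Terceira	spiders	Mermessus bryantae	tourist	abundant in surrounding pastures and exotic plantations
Terceira	spiders	Oedothorax fuscus	tourist	abundant in surrounding pastures
Terceira	spiders	Xysticus nubilus	tourist	common in adjacent open habitats
Terceira	spiders	Minicia floresensis	microhabitat_specialist	vegetation dweller, undersampled by ground-level traps
Terceira	spiders	Pisaura acoreensis	microhabitat_specialist	vegetation hunter, rarely at ground level
Terceira	spiders	Sancus acoreensis	microhabitat_specialist	orb-web builder on vegetation, rarely at ground level
Terceira	ground_beetles	Amara aenea	tourist	winged open-habitat species, common outside the forest
Terceira	ground_beetles	Anisodactylus binotatus	tourist	winged open-habitat species, common outside the forest
Terceira	ground_beetles	Ocys harpaloides	tourist	winged species of disturbed habitats nearby
Terceira	ground_beetles	Pterostichus vernalis	tourist	winged species of pastures and wetland margins
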