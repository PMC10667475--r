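species,genus,family,order
Quercus_ilex,Quercus,Fagaceae,Fagales
Erica_arborea,Erica,Ericaceae,Ericales
Cistus_salviifolius,Cistus,Cistaceae,Malvales
Arbutus_unedo,Arbutus,Ericaceae,Ericales
Phillyrea_latifolia,Phillyrea,Oleaceae,Lamiales
Pistacia_lentiscus,Pistacia,Anacardiaceae,Sapindales
Myrtus_communis,Myrtus,Myrtaceae,Myrtales
Juniperus_oxycedrus,Juniperus,Cupressaceae,Cupressales
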