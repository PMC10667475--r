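species,abundance
Quercus_ilex,182
Erica_arborea,95
Cistus_salviifolius,61
Arbutus_unedo,44
Phillyrea_latifolia,29
Pistacia_lentiscus,17
Myrtus_communis,9
Juniperus_oxycedrus,5
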