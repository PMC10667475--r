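(((Quercus_ilex:42,(Erica_arborea:18,Arbutus_unedo:18):24):15,((Cistus_salviifolius:30,Myrtus_communis:30):12,(Phillyrea_latifolia:25,Pistacia_lentiscus:25):17):15):38,Juniperus_oxycedrus:95);
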