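lineage_prefix	major	sub
root:Engineered	engineered	OTHER
root:Engineered:Biogas plant	engineered	biogas plant
root:Engineered:Bioreactor	engineered	bioreactor
root:Engineered:Bioremediation	engineered	bioremediation
root:Engineered:Food production	engineered	food production
root:Engineered:Solid waste	engineered	solid waste
root:Engineered:Wastewater	engineered	waste water
root:Environmental:Aquatic	environmental_aquatic	OTHER
root:Environmental:Aquatic:Aquaculture	environmental_aquatic	aquaculture
root:Environmental:Aquatic:Estuary	environmental_aquatic	estuary
root:Environmental:Aquatic:Freshwater	environmental_aquatic	freshwater
root:Environmental:Aquatic:Marine	environmental_aquatic	marine
root:Environmental:Aquatic:Thermal springs	environmental_aquatic	thermal springs
root:Host-associated	host_associated	OTHER
root:Host-associated:Human:Digestive system	host_associated	human digestive system
root:Host-associated:Human:Skin	host_associated	human skin
root:Host-associated:Mammals:Digestive system	host_associated	mammals digestive system
root:Host-associated:Mammals:Respiratory system	host_associated	mammals respiratory systems
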