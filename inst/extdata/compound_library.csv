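name,formula,neutral_mass,taxon
punicalagin,C48H28O30,,Terminalia;Combretaceae
punicalin,C34H22O22,,Terminalia;Combretaceae
corilagin,C27H22O18,,Terminalia;Combretaceae
chebulagic acid,C41H30O27,,Terminalia;Combretaceae
tellimagrandin I,C34H26O22,,Terminalia;Combretaceae
ellagic acid,C14H6O8,,Terminalia;Combretaceae
mono-O-galloylhexose,C13H16O10,,Terminalia;Combretaceae
penta-O-galloylhexose,C41H32O26,,Terminalia;Combretaceae
isovitexin,C21H20O10,,Terminalia;Combretaceae
isoorientin,C21H20O11,,Terminalia;Combretaceae
apigenin-6-C-(O-galloyl)-hexose,C28H24O14,,Terminalia;Combretaceae
luteolin-6-C-(O-galloyl)-hexose,C28H24O15,,Terminalia;Combretaceae
saponarin,C27H30O15,,Poaceae;generic
schaftoside,C26H28O14,,generic
rutin,C27H30O16,,generic
ursolic acid,C30H48O3,,Terminalia;Combretaceae
hydroxyursolic acid,C30H48O4,,Terminalia;Combretaceae
asiatic acid,C30H48O5,,Terminalia;Combretaceae
tetrahydroxyolean-12-en-28-oic acid,C30H48O6,,Terminalia;Combretaceae
trihydroxyursadien-28-oic acid,C30H46O5,,Terminalia;Combretaceae
"3-oxo-urs-12,18-dien-28-oic acid",C30H44O3,,Terminalia;Combretaceae
reserpine,C33H40N2O9,,standard
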