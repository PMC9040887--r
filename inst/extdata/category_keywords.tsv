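# Keyword-to-category rules, in priority order (first match wins).
# Categories: metabolism, signaling_cell_function, genetic_information_processing.
keyword	category	subcategory
polyketide synthase	metabolism	secondary_metabolism
nonribosomal peptide	metabolism	secondary_metabolism
terpene	metabolism	secondary_metabolism
cytochrome P450	metabolism	secondary_metabolism
methyltransferase	metabolism	tailoring
glycosyltransferase	metabolism	tailoring
oxidoreductase	metabolism	primary_metabolism
dehydrogenase	metabolism	primary_metabolism
hydrolase	metabolism	primary_metabolism
synthase	metabolism	primary_metabolism
kinase.*carbohydrate	metabolism	primary_metabolism
ABC transporter	signaling_cell_function	defense_transport
permease	signaling_cell_function	defense_transport
efflux	signaling_cell_function	defense_transport
antiporter	signaling_cell_function	defense_transport
DinB	signaling_cell_function	defense_transport
VOC family	signaling_cell_function	defense_transport
drug resistance	signaling_cell_function	defense_transport
cell wall	signaling_cell_function	cell_envelope
cell division	signaling_cell_function	cell_cycle
septum	signaling_cell_function	cell_cycle
two-component	signaling_cell_function	signal_transduction
histidine kinase	signaling_cell_function	signal_transduction
response regulator	signaling_cell_function	signal_transduction
sensor	signaling_cell_function	signal_transduction
sigma factor	genetic_information_processing	transcription
transcriptional regulator	genetic_information_processing	transcription
RNA polymerase	genetic_information_processing	transcription
ribosomal protein	genetic_information_processing	translation
tRNA	genetic_information_processing	translation
acetyltransferase	genetic_information_processing	modification
DNA glycosylase	genetic_information_processing	dna_repair
DNA repair	genetic_information_processing	dna_repair
helicase	genetic_information_processing	dna_replication_repair
DNA polymerase	genetic_information_processing	dna_replication_repair
recombinase	genetic_information_processing	dna_replication_repair
topoisomerase	genetic_information_processing	dna_replication_repair
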