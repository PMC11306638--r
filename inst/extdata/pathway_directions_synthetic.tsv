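pathway_id	term	direction_a	direction_b	available
GO:SYN0001	axon guidance	down	up	TRUE
GO:SYN0002	dendrite extension	down	up	TRUE
GO:SYN0003	axon development	down	up	TRUE
GO:SYN0004	dendritic spine organization	down	up	TRUE
GO:SYN0005	synapse assembly	down	up	TRUE
GO:SYN0006	CREB signaling	down	up	TRUE
GO:SYN0007	neurogenesis	up	down	TRUE
GO:SYN0008	chromatin organization	up	down	TRUE
GO:SYN0009	neuron migration	down	up	TRUE
GO:SYN0010	cell cycle	up	up	TRUE
GO:SYN0011	immune response	down	down	TRUE
GO:SYN0012	translation	 	 	FALSE
GO:SYN0013	lipid metabolic process	 	 	FALSE
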