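population	region	n_A	n_B	n_C	n_DRB1	H_A	H_B	H_C	H_DRB1
TundraNentsi	SIB	32	32	30	32	0.777	0.863	0.860	0.879
Chipewyan	NAM	50	50	50	50	0.685	0.888	0.895	0.890
Cree	NAM	36	36	36	36	0.793	0.852	0.903	0.903
Ojibwa	NAM	30	30	30	32	0.820	0.871	0.871	0.863
Mixtec	MEA	40	40	40	40	0.704	0.864	0.716	0.765
Mixe	MEA	40	40	40	40	0.708	0.809	0.736	0.782
Zapotec	MEA	40	34	32	36	0.730	0.927	0.797	0.878
Kaqchikel	MEA	38	38	38	38	0.844	0.922	0.861	0.881
Cabecar	MEA	38	38	38	38	0.770	0.676	0.637	0.709
Guaymi	MEA	36	36	36	36	0.660	0.716	0.619	0.671
Inga	SAA	30	28	30	30	0.780	0.855	0.773	0.853
Quechua	SAA	42	42	42	42	0.531	0.917	0.816	0.832
Aymara	SAA	40	40	40	40	0.622	0.816	0.688	0.775
Huilliche	SAA	40	40	30	40	0.809	0.778	0.782	0.848
Wayuu	SAL	30	30	28	30	0.889	0.878	0.865	0.873
Arhuaco	SAL	34	34	34	34	0.740	0.734	0.749	0.742
Kogi	SAL	30	28	28	28	0.658	0.694	0.617	0.684
Zenu	SAL	24	32	24	24	0.740	0.834	0.812	0.580
Embera	SAL	28	28	28	28	0.668	0.755	0.643	0.737
Waunana	SAL	40	40	40	40	0.560	0.849	0.784	0.691
TicunaArara	SAL	30	28	28	30	0.584	0.821	0.730	0.709
TicunaTarapaca	SAL	38	38	34	38	0.647	0.749	0.645	0.601
Guarani	SAL	20	20	18	18	0.805	0.785	0.759	0.753
Ache	SAL	26	22	16	24	0.541	0.550	0.398	0.295
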