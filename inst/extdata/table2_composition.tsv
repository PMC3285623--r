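taxon	phylum	superclade	length	A	C	G	T	at_percent	at_skew	gc_skew	rounding_note
Acropora tenuis	Cnidaria	Cnidaria	18338	0.251	0.137	0.242	0.37	62	-0.192	0.277	at_percent
Metridium senile	Cnidaria	Cnidaria	17443	0.269	0.169	0.212	0.349	61.9	-0.129	0.112	at_percent;gc_skew
Balanoglossus carnosus	Hemichordata	Deuterostomia	15708	0.251	0.314	0.171	0.264	51.4	-0.026	-0.295	at_percent;at_skew
Arbacia lixula	Echinodermata	Deuterostomia	15719	0.295	0.205	0.17	0.33	62.5	-0.057	-0.091	at_skew;gc_skew
Florometra serratissima	Echinodermata	Deuterostomia	16005	0.264	0.116	0.156	0.464	72.8	-0.274	0.149	at_skew;gc_skew
Homo sapiens	Chordata	Deuterostomia	16569	0.309	0.313	0.131	0.247	55.6	0.112	-0.41	
Xenopus laevis	Chordata	Deuterostomia	17553	0.331	0.235	0.135	0.3	63	0.049	-0.27	at_percent
Paraspadella gotoi	Chaetognatha	Lophotrochozoa	11423	0.394	0.147	0.125	0.334	72.8	0.081	-0.082	at_skew;gc_skew
Spadella cephaloptera	Chaetognatha	Lophotrochozoa	11905	0.364	0.182	0.167	0.286	65	0.12	-0.044	gc_skew
Priapulus caudatus	Priapulida	Ecdysozoa	14919	0.303	0.144	0.165	0.388	69.1	-0.123	0.068	
Caenorhabditis elegans	Nematoda	Ecdysozoa	13794	0.314	0.089	0.149	0.448	76.2	-0.175	0.253	at_skew;gc_skew
Trichinella spiralis	Nematoda	Ecdysozoa	16706	0.405	0.23	0.097	0.265	67	0.209	-0.405	gc_skew
Epiperipatus biolleyi	Onychophora	Ecdysozoa	14411	0.32	0.086	0.173	0.421	74.1	-0.135	0.334	at_skew;gc_skew
Limulus polyphemus	Arthropoda	Ecdysozoa	14985	0.375	0.227	0.097	0.301	67.6	0.111	-0.399	at_skew;gc_skew
Heptathela hangzhouensis	Arthropoda	Ecdysozoa	14215	0.416	0.172	0.106	0.369	78.6	0.059	-0.235	at_percent;at_skew;gc_skew
Antrokoreana gracilipes	Arthropoda	Ecdysozoa	14747	0.298	0.199	0.18	0.323	62.1	-0.041	-0.049	at_skew;gc_skew
Lithobius forficatus	Arthropoda	Ecdysozoa	15695	0.369	0.204	0.117	0.31	67.9	0.087	-0.269	gc_skew
Triops cancriformis	Arthropoda	Ecdysozoa	15101	0.358	0.182	0.131	0.33	68.8	0.041	-0.163	
Penaeus monodon	Arthropoda	Ecdysozoa	15984	0.353	0.167	0.127	0.354	70.6	-0.001	-0.136	at_percent
Atelura formicaria	Arthropoda	Ecdysozoa	15205	0.348	0.246	0.13	0.276	62.4	0.114	-0.308	at_skew;gc_skew
Tribolium castaneum	Arthropoda	Ecdysozoa	15881	0.398	0.185	0.098	0.319	71.7	0.109	-0.305	at_skew;gc_skew
Microcotyle sebastis	Platyhelminthes	Lophotrochozoa	14407	0.293	0.097	0.197	0.411	70.4	-0.166	0.341	at_skew;gc_skew
Echinococcus granulosus	Platyhelminthes	Lophotrochozoa	13588	0.191	0.08	0.25	0.479	67.1	-0.43	0.515	at_percent
Schistosoma japonicum	Platyhelminthes	Lophotrochozoa	14085	0.249	0.084	0.206	0.461	71	-0.299	0.422	gc_skew
Loxocorone allax	Entoprocta	Lophotrochozoa	14862	0.412	0.148	0.118	0.322	73.4	0.123	-0.111	gc_skew
Loxosomella aloxiata	Entoprocta	Lophotrochozoa	15323	0.392	0.163	0.131	0.314	70.6	0.11	-0.108	gc_skew
Flustrellidra hispida	Ectoprocta	Lophotrochozoa	13026	0.271	0.235	0.176	0.318	58.9	-0.079	-0.142	at_skew;gc_skew
Watersipora subtorquata	Ectoprocta	Lophotrochozoa	14144	0.364	0.163	0.131	0.342	70.6	0.03	-0.108	at_skew;gc_skew
Bugula neritina	Ectoprocta	Lophotrochozoa	15433	0.377	0.176	0.124	0.323	70	0.078	-0.173	at_skew
Flustra foliacea	Ectoprocta	Lophotrochozoa	16089	0.248	0.114	0.222	0.417	66.5	-0.254	0.321	
Phoronis psammophila	Phoronida	Lophotrochozoa	14018	0.334	0.168	0.166	0.332	66.6	0.002	-0.005	at_skew;gc_skew
Lingula anatina	Brachiopoda	Lophotrochozoa	28818	0.261	0.161	0.219	0.359	62	-0.158	0.153	
Terebratulina retusa	Brachiopoda	Lophotrochozoa	15451	0.295	0.277	0.151	0.277	57.2	0.033	-0.294	at_skew
Laqueus rubellus	Brachiopoda	Lophotrochozoa	14017	0.208	0.151	0.265	0.375	58.4	-0.286	0.272	at_percent;gc_skew
Terebratalia transversa	Brachiopoda	Lophotrochozoa	14291	0.199	0.134	0.275	0.392	59.1	-0.328	0.344	at_skew;gc_skew
Cephalothrix simula	Nemertea	Lophotrochozoa	16296	0.275	0.102	0.148	0.474	74.9	-0.266	0.182	gc_skew
Lineus viridis	Nemertea	Lophotrochozoa	15388	0.213	0.119	0.224	0.445	65.7	-0.352	0.306	at_percent;at_skew
Sipunculus nudus	Annelida	Lophotrochozoa	15502	0.268	0.297	0.161	0.274	54.2	-0.013	-0.297	at_skew
Clymenella torquata	Annelida	Lophotrochozoa	15538	0.33	0.195	0.133	0.343	67.2	-0.02	-0.188	at_percent;at_skew;gc_skew
Urechis caupo	Annelida	Lophotrochozoa	15113	0.315	0.235	0.144	0.305	62	0.016	-0.24	
Platynereis dumerilii	Annelida	Lophotrochozoa	15619	0.312	0.204	0.154	0.329	64.1	-0.026	-0.141	at_skew;gc_skew
Lumbricus terrestris	Annelida	Lophotrochozoa	14998	0.298	0.225	0.158	0.318	61.6	-0.031	-0.176	at_skew;gc_skew
Katharina tunicata	Mollusca	Lophotrochozoa	15532	0.314	0.119	0.186	0.38	69.4	-0.095	0.22	
Graptacme eborea	Mollusca	Lophotrochozoa	14492	0.37	0.132	0.127	0.371	74.1	-0.002	-0.021	at_skew;gc_skew
Nautilus macromphalus	Mollusca	Lophotrochozoa	16258	0.337	0.285	0.119	0.258	59.6	0.133	-0.412	at_percent;gc_skew
Loligo bleekeri	Mollusca	Lophotrochozoa	17211	0.388	0.195	0.092	0.325	71.3	0.089	-0.358	at_skew;gc_skew
Octopus vulgaris	Mollusca	Lophotrochozoa	15744	0.411	0.176	0.076	0.337	74.9	0.099	-0.397	at_percent
Pupa strigosa	Mollusca	Lophotrochozoa	14189	0.274	0.183	0.205	0.337	61.1	-0.103	0.056	gc_skew
Aplysia californica	Mollusca	Lophotrochozoa	14117	0.286	0.154	0.182	0.377	66.3	-0.137	0.085	gc_skew
Biomphalaria glabrata	Mollusca	Lophotrochozoa	13670	0.331	0.113	0.141	0.416	74.6	-0.114	0.11	at_percent
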