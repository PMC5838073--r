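breed	country	n	f	lnh_mb	shared_lnh_mb	decay	monophyletic	status	combined_with
Bergamasco Shepherd	NA	9	0.220	1843.258	382.935	0.450	TRUE	Breed	NA
Bolognese	NA	18	0.147	1848.889	251.647	0.336	TRUE	Breed	NA
Bracco Italiano	NA	9	0.139	1893.965	663.608	0.305	TRUE	Breed	NA
Cane Corso (Italy)	Italy	16	0.139	1803.263	178.954	0.380	FALSE	Variety	NA
Cane Corso (US)	US	4	0.141	1818.177	NA	NA	FALSE	NA	NA
Cirneco dell'Etna	NA	14	0.222	1952.620	418.463	0.241	TRUE	Breed	NA
Cane Paratore	NA	2	0.081	1862.197	NA	NA	FALSE	Insufficient	NA
Fonni's dog	NA	6	0.162	1839.483	452.063	0.629	TRUE	Breed	NA
Italian Greyhound (Italy)	Italy	10	0.250	1904.847	551.779	0.286	TRUE	Breed	Italian Greyhound (US)
Italian Greyhound (US)	US	10	0.290	1926.256	607.852	0.192	TRUE	NA	Italian Greyhound (Italy)
Lagotto Romagnolo	NA	18	0.171	1832.910	378.569	0.298	TRUE	Breed	NA
Levriero Meridionale	NA	2	0.220	1928.855	NA	NA	TRUE	Insufficient	NA
Lupino del Gigante	NA	10	0.141	1664.250	100.585	0.424	TRUE	Breed	NA
Lupo Italiano	NA	24	0.478	1988.448	1400.986	0.280	TRUE	Breed	NA
Mannara's Dog	NA	12	0.114	1887.253	167.485	0.497	FALSE	Variety	NA
Maremma Sheepdog	NA	14	0.124	1856.195	274.145	0.294	TRUE	Breed	NA
Mastino Abruzzese	NA	2	0.026	1815.659	NA	NA	FALSE	Insufficient	NA
Neapolitan Mastiff (Italy)	Italy	6	0.318	1897.332	NA	0.358	TRUE	Breed	Neapolitan Mastiff (US)
Neapolitan Mastiff (US)	US	6	0.296	1935.719	NA	0.292	TRUE	NA	Neapolitan Mastiff (Italy)
Pastore della Lessinia e del Lagorai	NA	10	0.079	1637.732	442.396	0.475	FALSE	Variety	NA
Pastore della Sila	NA	14	0.092	1856.336	385.056	0.665	TRUE	NotBreed	NA
Pastore d'Oropa	NA	15	0.043	1807.711	495.420	0.579	TRUE	Breed	NA
Segugio Italiano Pelo Forte	NA	16	0.088	1835.136	144.898	0.365	TRUE	Breed	Segugio Italiano Pelo Raso
Segugio Italiano Pelo Raso	NA	16	0.117	1880.337	189.692	0.351	TRUE	NA	Segugio Italiano Pelo Forte
Spinone Italiano	NA	16	0.136	1870.035	308.590	0.277	TRUE	Breed	NA
Volpino Italiano	NA	15	0.213	1912.347	361.279	0.299	FALSE	Variety	NA
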