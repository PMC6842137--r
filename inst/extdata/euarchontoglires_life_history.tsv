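species	common_name	mrls_years	body_mass_g	lq_percent	group
heterocephalus_glaber	Naked mole-rat	31	NA	368	glires
nannospalax_galili	Upper Galilee mountains blind mole rat	20.2	NA	190	glires
fukomys_damarensis	Damaraland mole-rat	15.5	NA	143	glires
chinchilla_lanigera	Long-tailed chinchilla	17.2	NA	131	glires
octodon_degus	Common degu	14	NA	124	glires
dipodomys_ordii	Kangaroo rat	9.9	NA	109	glires
peromyscus_maniculatus_bairdii	Northern American deer mouse	8.3	NA	107	glires
cavia_porcellus	Guinea pig	12	NA	89	glires
jaculus_jaculus	Lesser Egyptian jerboa	7.3	NA	81	glires
ictidomys_tridecemlineatus	Thirteen-lined ground squirrel	7.9	NA	73	glires
microtus_ochrogaster	Prairie vole	5.3	NA	61	glires
oryctolagus_cuniculus	European rabbit	9	NA	58	glires
mus_musculus	Mouse	4	NA	51	glires
cavia_aperea	Brazilian guinea pig	6	NA	50	glires
mesocricetus_auratus	Golden hamster	3.9	NA	39	glires
rattus_norvegicus	Common rat	3.8	NA	32	glires
homo_sapiens	Human	122.5	NA	463	primates
cebus_capucinus_imitator	White-headed capuchin	54.8	NA	331	primates
nomascus_leucogenys	Northern white-cheeked gibbon	44.1	NA	238	primates
pan_troglodytes	Chimpanzee	59.4	NA	236	primates
saimiri_boliviensis	Bolivian squirrel monkey	30.3	NA	232	primates
pan_paniscus	Bonobo	55	NA	222	primates
pongo_abelii	Sumatran orangutan	59	NA	221	primates
aotus_nancymaae	Nancy Ma's night monkey	30	874	218	primates
macaca_fascicularis	Crab-eating macaque	39	NA	209	primates
macaca_mulatta	Macaque	40	NA	206	primates
gorilla_gorilla_gorilla	Western lowland gorilla	60.1	NA	200	primates
callithrix_jacchus	Marmoset	22.8	NA	200	primates
microcebus_murinus	Mouse lemur	18.2	NA	197	primates
macaca_nemestrina	Pigtail macaque	37.6	NA	194	primates
colobus_angolensis_palliatus	Angola colobus	35.3	NA	180	primates
mandrillus_leucophaeus	Drill	39	NA	177	primates
chlorocebus_sabaeus	Green monkey	31.6	5620	173	primates
propithecus_coquereli	Coquerel's sifaka	30.5	5000	170	primates
carlito_syrichta	Philippine tarsier	16	NA	157	primates
rhinopithecus_roxellana	Golden snub-nosed monkey	29.5	NA	139	primates
otolemur_garnettii	Bushbaby	20	NA	136	primates
cercocebus_atys	Sooty mangabey	26.8	9390	135	primates
papio_anubis	Olive baboon	25.2	NA	114	primates
rhinopithecus_bieti	Black snub-nosed monkey	15	9960	75	primates
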