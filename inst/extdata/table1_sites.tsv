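site_id	lat_dms	lon_dms	n_eos	n_hyb	n_neo	n_private	shared_lineages	lgs_category	sampling_ref
RI-2-4	45°03′01″	72°19′03″	31	40	0	3		150-160	1
SF-3,18	45°03′05″	72°11′39″	0	5	0	1		150-160	1
SF-11	45°04′23″	71°52′37″	0	2	0	1		150-160	1
SF-12	45°07′48″	71°40′21″	28	51	12	2		150-160	1
SF-13,14	45°11′04″	71°33′13″	14	114	0	3	A	150-160	1
SF-9-10	45°12′23″	71°56′33″	30	0	0	0		150-160	1
SF-6	45°13′20″	71°55′01″	9	0	0	0		150-160	1
SF-4,5,7,8	45°14′01″	71°54′28″	12	54	0	2		150-160	1
RI-1	45°15′03″	72°18′20″	0	4	0	1		150-160	1
SF-2	45°21′17″	72°13′05″	14	7	0	2		150-160	1
CH-1	45°22′48″	70°50′02″	0	1	3	1		140-150	1
YA-1	45°23′23″	72°27′01″	10	24	0	2	B	150-160	1
YA-2	45°24′25″	72°25′18″	24	0	0	0		150-160	1
SF-15	45°24′53″	71°46′53″	0	6	0	3		140-150	1
SF-20,21	45°25′50″	71°40′19″	2	24	0	6		140-150	1
SF-1	45°27′00″	71°49′32″	16	14	0	5	A	140-150	1
CH-2	45°29′03″	71°04′48″	80	0	0	0		140-150	1
SF-19,22	45°32′15″	71°49′40″	0	12	0	1	B	140-150	1
CH-3	45°41′10″	70°55′01″	1	47	0	3	C,D	140-150	2
SF-16,17	45°42′10″	71°09′59″	0	6	0	2		140-150	1
CH-4	45°46′59″	70°51′13″	13	24	4	13	D,E	140-150	2
CH-5	45°50′45″	70°53′19″	19	16	29	5	E	140-150	2
CH-6	45°56′02″	70°47′37″	3	4	0	1		140-150	2
CH-7	46°06′29″	70°24′50″	7	21	0	2	C	130-140	2
SJ-1	46°10′52″	70°18′19″	10	15	11	2	F	130-140	2
SJ-2	46°11′22″	70°18′40″	21	16	7	2	F	130-140	2
SJ-3	46°20′40″	70°14′48″	8	2	0	0	G	130-140	2
SJ-4	46°32′42″	70°14′38″	5	3	2	0	F,G	130-140	2
SJ-5	46°39′05″	70°14′35″	0	4	23	0	F	130-140	2
SJ-6	46°40′19″	70°10′16″	4	0	0	0		130-140	2
SJ-7	46°48′54″	70°13′45″	21	12	0	2	F,G	130-140	2
SJ-8	46°51′27″	70°10′12″	1	11	10	1	F,H	130-140	2
SJ-9	46°51′45″	70°10′37″	17	2	3	0	G	130-140	2
SJ-10	46°54′33″	70°14′23″	3	8	0	0	F,G,H	130-140	2
SJ-11	46°55′50″	70°04′22″	4	0	0	0		130-140	2
OU-1	47°05′23″	69°51′50″	17	4	3	0	F,H	130-140	2
OU-2	47°06′31″	69°53′52″	15	2	9	0	H	130-140	2
OU-3	47°06′32″	70°00′30″	9	0	7	0		130-140	2
OU-4	47°07′33″	69°50′40″	0	2	0	0	F	130-140	2
OU-5	47°09′12″	69°48′26″	25	22	1	2		130-140	2
LO-1	47°30′44″	69°32′24″	12	0	0	0		130-140	2
LO-2	47°32′15″	69°35′07″	8	0	4	0		130-140	2
SJ-12	47°42′05″	68°59′36″	0	6	0	1		130-140	2
SJ-13	47°55′03″	68°57′16″	0	0	1	0		130-140	2
SJ-14	47°55′41″	68°50′53″	1	0	0	0		130-140	2
RM-1	48°05′02″	68°32′47″	2	0	0	0		120-130	2
RM-2	48°06′43″	68°31′50″	2	0	0	0		120-130	2
RM-3	48°08′05″	68°25′04″	12	0	6	0		120-130	2
MI-2	48°18′15″	68°14′32″	2	0	0	0		120-130	2
MI-1	48°19′33″	68°18′54″	3	0	1	0		120-130	2
MI-3	48°29′38″	68°14′27″	16	1	0	1		120-130	2
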