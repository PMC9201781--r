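code	locality	lon	lat	elev_m	status	haplotype	count
NUJ	Nujiang, Yunnan, China	99.10	25.78	2204	wild	H1	10
YAN	Yanjin, Yunnan, China	104.32	28.16	997	cultivated	H1	4
YAN	Yanjin, Yunnan, China	104.32	28.16	997	cultivated	H3	3
JUL	Junlian, Sichuan, China	104.48	28.19	393	cultivated	H1	10
QIC	Qingchuan, Sichuan, China	105.19	32.58	1099	wild	H1	10
CHI	Chishui, Guizhou, China	105.86	28.29	1271	wild	H1	3
KKS	Suiyang, Guizhou, China	107.20	28.18	1242	wild	H1	10
DSH	Daozhen, Guizhou, China	107.73	29.14	1304	wild	H1	10
LGS	Leishan, Guizhou, China	108.16	26.37	1204	wild	H1	10
FJS	Jiangkou, Guizhou, China	108.61	27.87	1005	wild	H1	10
BYS	Baojing, Hunan, China	109.33	28.71	436	wild	H1	3
BYS	Baojing, Hunan, China	109.33	28.71	436	cultivated	H3	8
BDG	Sangzhi, Hunan, China	110.09	29.78	1336	wild	H1	10
YUN	Wugang, Hunan, China	110.61	26.65	1166	wild	H1	3
YUN	Wugang, Hunan, China	110.61	26.65	1166	cultivated	H3	8
LIC	Lichuan, Hubei, China	109.06	30.03	829	wild	H1	1
LIC	Lichuan, Hubei, China	109.06	30.03	829	cultivated	H1	2
XDS	Lichuan, Hubei, China	109.10	30.03	1019	wild	H1	9
XDS	Lichuan, Hubei, China	109.10	30.03	1019	wild	H4	1
BDO	Badong, Hubei, China	110.18	30.70	1378	wild	H1	2
MPX	Zigui, Hubei, China	110.43	30.82	1100	wild	H1	10
WUF	Wufeng, Hubei, China	111.05	30.17	296	wild	H1	3
WUF	Wufeng, Hubei, China	111.05	30.17	296	cultivated	H1	1
CHE	Chengkou, Chongqing, China	108.80	31.67	2294	wild	H1	6
BPX	Chengkou, Chongqing, China	108.80	31.99	1140	wild	H1	10
XLS	Maiji, Gansu, China	106.00	34.36	1397	wild	H1	10
MEI	Meixian, Shaanxi, China	107.95	34.12	692	wild	H1	7
MEI	Meixian, Shaanxi, China	107.95	34.12	692	wild	H2	1
FOP	Foping, Shaanxi, China	107.98	33.51	895	wild	H1	3
FOP	Foping, Shaanxi, China	107.98	33.51	895	cultivated	H1	2
FOP	Foping, Shaanxi, China	107.98	33.51	895	cultivated	H3	7
SHT	Langao, Shaanxi, China	108.80	32.05	2409	wild	H1	10
SJZ	Langao, Shaanxi, China	108.88	32.27	741	wild	H1	10
ZHA	Zhashui, Shaanxi, China	109.05	33.86	1178	wild	H1	8
ZHA	Zhashui, Shaanxi, China	109.05	33.86	1178	wild	H2	2
BXZ	Pingli, Shaanxi, China	109.31	32.03	1637	wild	H1	10
LUS	Lushi, Henan, China	110.90	34.21	1194	wild	H1	10
LUC	Luanchuan, Henan, China	111.71	33.80	1542	wild	H1	4
LUC	Luanchuan, Henan, China	111.71	33.80	1542	cultivated	H1	6
YUT	Xiuwu, Henan, China	113.37	35.45	1016	wild	H1	5
JIK	Jiaokou, Shanxi, China	111.23	36.78	1348	wild	H1	10
XIA	Xiaxian, Shanxi, China	111.39	35.09	936	wild	H1	10
LIS	Qinshui, Shanxi, China	112.05	35.43	1510	wild	H1	10
LKS	Qinyuan, Shanxi, China	112.07	36.59	1582	wild	H1	10
WUA	Wu'an, Hebei, China	113.87	36.81	694	wild	H1	1
WUA	Wu'an, Hebei, China	113.87	36.81	694	cultivated	H1	4
QBG	Wu'an, Hebei, China	113.88	36.94	752	wild	H1	10
ZSY	Zanhuang, Hebei, China	114.04	37.46	977	wild	H1	10
ZAN	Zanhuang, Hebei, China	114.23	37.72	1045	wild	H1	2
AHH	Huangshan, Anhui, China	118.02	30.14	293	wild	H3	1
AHH	Huangshan, Anhui, China	118.02	30.14	293	wild	H5	4
ZAO	Zaozhuang, Shandong, China	117.52	35.11	229	wild	H3	12
ZAO	Zaozhuang, Shandong, China	117.52	35.11	229	cultivated	H5	2
SZB	Boshan, Shandong, China	118.04	36.31	484	wild	H3	9
SZB	Boshan, Shandong, China	118.04	36.31	484	wild	H5	2
YTS	Qingzhou, Shandong, China	118.28	36.46	599	wild	H3	11
KYS	Yantai, Shandong, China	121.73	37.27	209	wild	H3	7
BEN	Benxi, Liaoning, China	123.87	41.32	269	wild	H3	14
HUA	Huanren, Liaoning, China	125.49	41.02	230	wild	H3	3
TSS	Xuyi, Jiangsu, China	118.45	32.73	97	wild	H3	6
JIA	Jiande, Zhejiang, China	119.52	29.44	47	cultivated	H5	4
ZHZ	Hangzhou, Zhejiang, China	120.03	30.22	48	cultivated	H1	3
OKC	Okcheon, North Chungcheong, South Korea	127.64	36.33	194	cultivated	H3	4
WNJ	Wonju, Gangwon, South Korea	127.91	37.35	156	cultivated	H3	2
SED	Soeda, Fukuoka, Japan	130.87	33.49	249	cultivated	H3	1
HIT	Hita, Oita, Japan	130.94	33.41	261	cultivated	H3	2
TKD	Taketa, Oita, Japan	131.41	32.97	321	cultivated	H3	3
BGO	Bungo-ono, Oita, Japan	131.49	32.99	175	cultivated	H3	1
TNO	Tsuno, Kochi, Japan	133.02	33.45	494	cultivated	H3	2
TSY	Kochi, Kochi, Japan	133.51	33.64	197	cultivated	H3	1
OTY	Otoyo, Kochi, Japan	133.68	33.84	427	cultivated	H3	1
BCU	Takahashi, Okayama, Japan	133.39	34.83	317	cultivated	H3	1
NIM	Niimi, Okayama, Japan	133.52	34.89	281	cultivated	H3	2
YSR	Miyoshi, Tokushima, Japan	133.75	33.96	216	cultivated	H3	1
YKN	Fukuchiyama, Kyoto, Japan	134.94	35.32	154	cultivated	H3	1
NYN	Gojo, Nara, Japan	135.73	34.29	193	cultivated	H3	2
SNI	Soni, Nara, Japan	136.14	34.50	592	cultivated	H3	2
MSG	Tsu, Mie, Japan	136.27	34.55	227	cultivated	H3	2
SKW	Shirakawa, Gifu, Japan	136.91	36.26	570	cultivated	H3	1
HID	Hida, Gifu, Japan	137.22	36.34	949	cultivated	H3	2
WJM	Wajima, Ishikawa, Japan	136.89	37.33	123	cultivated	H3	3
SZU	Suzu, Ishikawa, Japan	137.14	37.40	213	cultivated	H3	1
MNM	Minakami, Gunma, Japan	138.99	36.70	516	cultivated	H3	1
KKR	Kamakura, Kanagawa, Japan	139.51	35.31	14	cultivated	H3	1
OGN	Oguni, Yamagata, Japan	139.81	38.09	209	cultivated	H3	2
AZW	Aizuwakamatsu, Fukushima, Japan	139.97	37.51	405	cultivated	H3	1
DIG	Daigo, Ibaraki, Japan	140.40	36.70	145	cultivated	H3	1
OWN	Owani, Aomori, Japan	140.53	40.49	121	cultivated	H3	1
AMS	Aomori, Aomori, Japan	140.67	40.78	76	cultivated	H3	2
SNG	Shingo, Aomori, Japan	141.18	40.43	158	cultivated	H3	1
SDI	Sendai, Miyagi, Japan	140.85	38.26	59	cultivated	H3	1
JBJ	Ninohe, Iwate, Japan	141.18	40.16	435	cultivated	H3	1
INH	Ichinohe, Iwate, Japan	141.31	40.20	197	cultivated	H3	3
ABS	Abashiri, Hokkaido, Japan	144.25	44.01	145	cultivated	H3	2
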