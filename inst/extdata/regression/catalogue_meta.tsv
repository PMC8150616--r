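id	contig	start	end	length	observations	AFR	EAS	EUR	pop_CHB	pop_GBR	pop_LWK	allele
HAP1	regfix1	189	409	221	2	2	0	0	0	0	2	AL*01
HAP2	regfix1	201	415	215	2	0	2	0	2	0	0	AL*03
HAP3	regfix1	201	475	275	2	0	2	0	2	0	0	AL*02
HAP4	regfix1	1	409	409	1	0	1	0	1	0	0	AL*01
HAP5	regfix1	1	409	409	1	0	1	0	1	0	0	AL*02
HAP6	regfix1	1	600	600	1	0	1	0	1	0	0	AL*01
HAP7	regfix1	1	600	600	1	0	1	0	1	0	0	AL*01
HAP8	regfix1	87	493	407	1	0	1	0	1	0	0	unclassified
HAP9	regfix1	87	493	407	1	0	1	0	1	0	0	AL*01
HAP10	regfix1	101	565	465	1	0	1	0	1	0	0	AL*01
HAP11	regfix1	101	565	465	1	0	1	0	1	0	0	AL*01
HAP12	regfix1	141	415	275	1	1	0	0	0	0	1	AL*03
HAP13	regfix1	141	415	275	1	1	0	0	0	0	1	AL*01
HAP14	regfix1	159	600	442	1	0	0	1	0	1	0	AL*01
HAP15	regfix1	159	600	442	1	0	0	1	0	1	0	AL*01
HAP16	regfix1	177	415	239	1	0	0	1	0	1	0	AL*03
HAP17	regfix1	177	415	239	1	0	0	1	0	1	0	unclassified
HAP18	regfix1	201	415	215	1	0	0	1	0	1	0	AL*01
HAP19	regfix1	201	415	215	1	0	0	1	0	1	0	AL*01
HAP20	regfix1	201	421	221	1	1	0	0	0	0	1	AL*01
HAP21	regfix1	201	421	221	1	1	0	0	0	0	1	AL*01
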