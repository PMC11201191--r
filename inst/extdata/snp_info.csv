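snp_id,trait,year,p_source,base_pair,risk_allele,other_allele,beta,gene
rs1541518,Non-word reading,2019,6e-8,31108665,G,,0.177,ADCYAP1R1
rs281238,Phoneme awareness,2019,1e-7,47432075,T,C,0.156,SEMA6D
rs4571421,Rapid automatized naming of pictures,2019,3e-7,188588642,C,,0.168,LINC02118
rs7301219,Rapid automatized naming of pictures,2019,5e-7,43731097,C,,0.151,
rs9925265,Phoneme awareness,2019,4.51e-7,126496851,G,,0.148,SLC12A3
rs7187223,Non-word reading,2013,1e-7,82424128,A,,0.251,
rs764255,Word reading,2013,1.8e-7,72271184,T,,-0.077,ZFHX3
rs6963842,Rapid automatized naming of letters,2019,2e-7,107994544,G,,0.02,LAMB1
rs9540938,Latent naming speed,2019,5e-7,66867593,A,,,PCDH9
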