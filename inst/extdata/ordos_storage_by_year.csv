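year,image,mean_density_tha,min_density_tha,max_density_tha,total_t
2023,Sentinel 2A,20.36,2.09,58.52,25925488.23
2023,Landsat 8 approach 1,20.56,2.29,70.70,40544080.50
2023,Landsat 8 approach 2,19.78,3.59,49.20,26735429.73
2013,Landsat 8 approach 2,16.55,2.59,49.62,13715729.12
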