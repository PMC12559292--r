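class,mean_density_tha,min_density_tha,max_density_tha,total_t
Populus,29.14,8.23,58.52,4506024.85
Salix,27.39,2.09,49.66,1197381.53
Pinus tabuliformis,13.00,7.39,27.57,825591.21
Other species and types,23.24,9.50,31.95,2150570.97
Shrub,9.02,5.80,14.25,17245919.68
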