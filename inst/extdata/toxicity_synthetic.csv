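compound,species,endpoint_type,value,unit,medium,kd
tetracycline,synthetic_soil_microbe_A,EC50,60000,ug/kg,soil,NA
tetracycline,synthetic_plant_A,NOEC,4000,ug/kg,soil,NA
tetracycline,synthetic_alga_A,EC50,30,ug/L,water,1400
chlortetracycline,synthetic_soil_microbe_A,EC50,80000,ug/kg,soil,NA
chlortetracycline,synthetic_earthworm_A,LC50,55000,ug/kg,soil,NA
oxytetracycline,synthetic_plant_B,EC50,45000,ug/kg,soil,NA
oxytetracycline,synthetic_soil_microbe_B,NOEC,3500,ug/kg,soil,NA
doxycycline,synthetic_soil_microbe_A,EC50,70000,ug/kg,soil,NA
doxycycline,synthetic_alga_B,EC50,40,ug/L,water,1600
ofloxacin,synthetic_cyanobacterium_A,EC50,21,ug/L,water,1200
ofloxacin,synthetic_plant_A,NOEC,6000,ug/kg,soil,NA
norfloxacin,synthetic_soil_microbe_B,EC50,90000,ug/kg,soil,NA
norfloxacin,synthetic_plant_C,NOEC,5000,ug/kg,soil,NA
ciprofloxacin,synthetic_cyanobacterium_A,EC50,17,ug/L,water,2500
ciprofloxacin,synthetic_soil_microbe_A,NOEC,8000,ug/kg,soil,NA
enrofloxacin,synthetic_plant_B,EC50,65000,ug/kg,soil,NA
enrofloxacin,synthetic_earthworm_A,LC50,48000,ug/kg,soil,NA
lomefloxacin,synthetic_soil_microbe_B,EC50,75000,ug/kg,soil,NA
lomefloxacin,synthetic_plant_A,NOEC,4500,ug/kg,soil,NA
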