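archetype,alpha,y,t_min,t_opt,t_max,vpd_coeff,max_age,a_stem,n_stem,n_conc_foliage,n_conc_root,n_conc_stem,p_to_n_ratio,sla,k,wood_density,root_alloc_min,root_alloc_max,foliage_share_ag,turnover_foliage,turnover_root
eucalypt,1.5e-06,0.47,8,25,40,0.5,50,0.095,2.4,30,12,6,0.1,6,0.5,0.5,0.2,0.6,0.35,0.027,0.015
poplar,1.45e-06,0.47,1,18,35,0.55,60,0.11,2.35,28,11,5,0.1,12,0.5,0.35,0.2,0.6,0.35,0.03,0.015
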