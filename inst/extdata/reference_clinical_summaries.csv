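measure,n_mrp,mean_mrp,sd_mrp,n_msp,mean_msp,sd_msp
age,14,61.0,7.0,15,62.6,8.3
duration,14,14.3,7.6,15,9.0,7.4
pre_vas,14,6.9,1.1,15,6.1,1.4
post_vas,14,6.9,1.5,15,2.4,0.6
pre_psqi,14,8.9,3.7,15,8.4,5.7
post_psqi,14,7.4,3.9,15,3.7,1.6
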