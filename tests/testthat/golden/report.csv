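characteristic,n,ppv,npv,alpha,corr,corr_method,p
self_efficacy,182,0.571,0.798,0.860,0.418,spearman,0.001
coping,171,0.415,0.944,N.A.,N.A.,N.A.,N.A.
depression,192,0.679,0.994,0.870,0.805,spearman,0.001
anxiety,182,0.778,0.913,0.560,0.653,spearman,0.001
locus,147,0.676,0.533,0.020,0.472,spearman,0.001
social_support,191,N.A.,N.A.,0.630,0.626,spearman,0.001
burden,163,N.A.,N.A.,N.A.,0.554,spearman,0.001
coping_P,171,N.A.,N.A.,0.700,0.746,spearman,0.001
coping_E,171,N.A.,N.A.,0.730,0.800,spearman,0.001
coping_D,171,N.A.,N.A.,0.560,0.783,spearman,0.001
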