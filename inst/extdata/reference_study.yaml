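# Full coverage/RMSE study design: six reference distributions, the sample
# size grid 50(50)200, 250(250)1000, the classical estimator plus all six
# nonparametric quantile estimators, 5000 Monte-Carlo replicates per cell.
distributions: [normal, lognormal, beta_2_5, beta_2_2, chisq_4, exp_1]
sample_sizes: [50, 100, 150, 200, 250, 500, 750, 1000]
estimators: [ba, sq, hd, bp, hdlc, sv, "no"]
replicates: 5000
seed: 1
lognormal_meanlog: 0
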