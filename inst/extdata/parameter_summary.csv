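parameter,mean_psg,sd_psg,mean_dev,sd_dev,cohens_d,bias,bias_sd
tib_min,443.58,44.98,NA,NA,NA,NA,NA
tspd_min,408.05,57.13,406.16,51.27,0.250,1.89,44.97
tst_min,344.62,79.58,374.17,72.42,-0.407,-29.54,72.54
waso_min,63.42,57.42,31.99,51.64,0.442,31.44,71.13
awakenings_n,3.64,2.27,0.69,0.94,1.15,2.95,2.57
sol_min,31.64,33.97,40.26,42.59,-0.206,-8.62,53.76
se_pct,78.32,16.56,84.14,15.70,-0.329,-5.82,17.67
light_min,214.79,55.12,244.62,56.59,-0.439,-29.81,67.98
deep_min,60.72,29.41,75.37,31.73,-0.385,-14.64,59.97
rem_min,69.11,28.08,49.61,30.70,0.536,19.49,36.40
awake_min,94.86,71.88,66.51,66.22,0.390,28.36,72.69
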