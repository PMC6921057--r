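# Published per-population evaluation summaries (mean obs/pred ratio with
# range, AFE, RMSE).  The *_ok columns mark which printed cells are
# recoverable from the printed observed/predicted pairs: "no" means the
# published cell was computed from unrounded values or from profiles not
# printed in the pair table (not_reproducible_from_printed_inputs).
population,route,parameter,mean_ratio,ratio_lo,ratio_hi,afe,rmse,mean_ok,afe_ok,rmse_ok
healthy,iv,AUC_0_inf,0.82,0.76,0.89,0.78,19.39,yes,no,no
healthy,iv,CL,1.28,1.26,1.31,1.27,1.78,yes,yes,yes
healthy,iv,Cmax,1.16,1.04,1.27,1.14,1.96,yes,yes,yes
healthy,oral,AUC_0_inf,0.84,0.51,1.47,0.80,51.80,no,no,no
healthy,oral,CL,1.22,0.65,1.86,1.14,2.83,no,no,no
healthy,oral,Cmax,0.88,0.36,1.67,0.79,5.95,no,no,no
tuberculosis,oral,AUC_0_inf,0.96,0.69,1.31,0.93,16.10,no,no,no
tuberculosis,oral,CL,1.08,0.76,1.42,1.02,1.04,no,no,no
tuberculosis,oral,Cmax,0.69,0.46,0.85,0.66,13.82,no,no,no
cirrhosis,oral,AUC_0_inf,1.09,0.87,1.38,1.30,11.27,yes,no,yes
cirrhosis,oral,CL,0.94,0.72,1.14,0.98,0.009,no,no,no
cirrhosis,oral,Cmax,1.19,0.99,1.46,1.10,2.67,yes,no,yes
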