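# Transcription of the published observed vs predicted PK parameter table
# (healthy, tuberculosis, cirrhosis; single-dose i.v. and oral rifampicin).
# flag: "" = usable pair; tb_aggregate = tuberculosis rows whose published
# summary statistics derive from profiles not printed in the table (the
# 600 mg predicted CL of 0.9 L/h is additionally a probable typo).
population,route,dose_label,parameter,observed,predicted,flag
healthy,iv,450 mg,AUC_0_inf,52.49,58.16,
healthy,iv,600 mg,AUC_0_inf,73.50,96.38,
healthy,iv,450 mg,CL,7.86,6.23,
healthy,iv,600 mg,CL,8.15,6.22,
healthy,iv,450 mg,Cmax,12.53,9.80,
healthy,iv,600 mg,Cmax,13.61,13.07,
healthy,oral,300 mg,AUC_0_inf,29.93,40.19,
healthy,oral,450 mg,AUC_0_inf,42.04,60.20,
healthy,oral,600 mg,AUC_0_inf,76.95,81.06,
healthy,oral,10 mg/kg,AUC_0_inf,68.85,86.20,
healthy,oral,300 mg,CL,9.98,7.38,
healthy,oral,450 mg,CL,10.77,7.44,
healthy,oral,600 mg,CL,8.25,7.44,
healthy,oral,10 mg/kg,CL,0.145,0.115,
healthy,oral,300 mg,Cmax,5.37,5.47,
healthy,oral,450 mg,Cmax,5.88,9.08,
healthy,oral,600 mg,Cmax,9.85,10.30,
healthy,oral,10 mg/kg,Cmax,10.8,10.55,
tuberculosis,oral,450 mg,AUC_0_inf,65.52,64.67,tb_aggregate
tuberculosis,oral,600 mg,AUC_0_inf,93.40,86.70,tb_aggregate
tuberculosis,oral,10 mg/kg,AUC_0_inf,66.7,95.3,tb_aggregate
tuberculosis,oral,450 mg,CL,7.15,6.92,tb_aggregate
tuberculosis,oral,600 mg,CL,6.4,0.9,tb_aggregate
tuberculosis,oral,10 mg/kg,CL,0.14,0.10,tb_aggregate
tuberculosis,oral,450 mg,Cmax,8.30,11.45,tb_aggregate
tuberculosis,oral,600 mg,Cmax,13.3,15.6,tb_aggregate
tuberculosis,oral,10 mg/kg,Cmax,8.50,18.4,tb_aggregate
cirrhosis,oral,4 mg/kg,AUC_0_inf,29.6,33.8,
cirrhosis,oral,6 mg/kg,AUC_0_inf,70.4,50.7,
cirrhosis,oral,8 mg/kg,AUC_0_inf,65.2,67.6,
cirrhosis,oral,10 mg/kg,AUC_0_inf,95.1,84.5,
cirrhosis,oral,4 mg/kg,CL,0.135,0.113,
cirrhosis,oral,6 mg/kg,CL,0.085,0.113,
cirrhosis,oral,8 mg/kg,CL,0.122,0.113,
cirrhosis,oral,10 mg/kg,CL,0.105,0.113,
cirrhosis,oral,4 mg/kg,Cmax,5.50,5.52,
cirrhosis,oral,6 mg/kg,Cmax,12.10,8.28,
cirrhosis,oral,8 mg/kg,Cmax,11.70,11.04,
cirrhosis,oral,10 mg/kg,Cmax,17.40,13.80,
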