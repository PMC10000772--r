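source,group,variable,numerator,denominator,printed_pct,digits
table1,overall,age_lt36,349,2658,13.1,1
table1,overall,age_36_55,1637,2658,61.6,1
table1,overall,age_gt55,672,2658,25.3,1
table1,overall,male,1903,2658,71.6,1
table1,overall,depression,196,2658,7.4,1
table1,overall,respiratory_disease,422,2658,15.9,1
table1,overall,renal_failure,35,2658,1.3,1
table1,overall,alcohol_drug_abuse,104,2658,3.9,1
table1,overall,cardiovascular_disease,65,2658,2.4,1
table1,overall,diabetes,93,2658,3.5,1
table1,overall,dyslipidemia,298,2658,11.2,1
table1,overall,hbv_hcv,207,2658,7.8,1
table1,overall,hypertension,519,2658,19.5,1
table1,overall,cci_0,2318,2658,87.2,1
table1,overall,cci_1,275,2658,10.3,1
table1,overall,cci_ge2,65,2658,2.4,1
table1,2015,age_lt36,103,966,10.7,1
table1,2015,age_36_55,649,966,67.2,1
table1,2015,age_gt55,214,966,22.2,1
table1,2015,male,691,966,71.5,1
table1,2015,depression,68,966,7,1
table1,2015,respiratory_disease,152,966,15.7,1
table1,2015,renal_failure,8,966,0.8,1
table1,2015,alcohol_drug_abuse,30,966,3.1,1
table1,2015,cardiovascular_disease,19,966,2,1
table1,2015,diabetes,34,966,3.5,1
table1,2015,dyslipidemia,131,966,13.6,1
table1,2015,hbv_hcv,71,966,7.3,1
table1,2015,hypertension,178,966,18.4,1
table1,2015,cci_0,840,966,87,1
table1,2015,cci_1,96,966,9.9,1
table1,2015,cci_ge2,30,966,3.1,1
table1,2016,age_lt36,89,814,10.9,1
table1,2016,age_36_55,533,814,65.5,1
table1,2016,age_gt55,192,814,23.6,1
table1,2016,male,598,814,73.5,1
table1,2016,depression,73,814,9,1
table1,2016,respiratory_disease,127,814,15.6,1
table1,2016,renal_failure,14,814,1.7,1
table1,2016,alcohol_drug_abuse,30,814,3.7,1
table1,2016,cardiovascular_disease,20,814,2.5,1
table1,2016,diabetes,35,814,4.3,1
table1,2016,dyslipidemia,101,814,12.4,1
table1,2016,hbv_hcv,73,814,9,1
table1,2016,hypertension,178,814,21.9,1
table1,2016,cci_0,737,814,90.5,1
table1,2016,cci_1,60,814,7.4,1
table1,2016,cci_ge2,17,814,2.1,1
table1,2017,age_lt36,177,1566,11.3,1
table1,2017,age_36_55,963,1566,61.5,1
table1,2017,age_gt55,426,1566,27.2,1
table1,2017,male,1129,1566,72.1,1
table1,2017,depression,122,1566,7.8,1
table1,2017,respiratory_disease,351,1566,22.4,1
table1,2017,renal_failure,27,1566,1.7,1
table1,2017,alcohol_drug_abuse,55,1566,3.5,1
table1,2017,cardiovascular_disease,63,1566,4,1
table1,2017,diabetes,71,1566,4.5,1
table1,2017,dyslipidemia,225,1566,14.4,1
table1,2017,hbv_hcv,154,1566,9.8,1
table1,2017,hypertension,355,1566,22.7,1
table1,2017,cci_0,1354,1566,86.5,1
table1,2017,cci_1,172,1566,11,1
table1,2017,cci_ge2,40,1566,2.6,1
table1,2018,age_lt36,228,2198,10.4,1
table1,2018,age_36_55,1303,2198,59.3,1
table1,2018,age_gt55,667,2198,30.3,1
table1,2018,male,1563,2198,71.1,1
table1,2018,depression,172,2198,7.8,1
table1,2018,respiratory_disease,397,2198,18.1,1
table1,2018,renal_failure,35,2198,1.6,1
table1,2018,alcohol_drug_abuse,99,2198,4.5,1
table1,2018,cardiovascular_disease,83,2198,3.8,1
table1,2018,diabetes,92,2198,4.2,1
table1,2018,dyslipidemia,290,2198,13.2,1
table1,2018,hbv_hcv,196,2198,8.9,1
table1,2018,hypertension,524,2198,23.8,1
table1,2018,cci_0,1924,2198,87.5,1
table1,2018,cci_1,220,2198,10,1
table1,2018,cci_ge2,54,2198,2.5,1
table1,2019,age_lt36,161,1583,10.2,1
table1,2019,age_36_55,860,1583,54.3,1
table1,2019,age_gt55,562,1583,35.5,1
table1,2019,male,1145,1583,72.3,1
table1,2019,depression,134,1583,8.5,1
table1,2019,respiratory_disease,212,1583,13.4,1
table1,2019,renal_failure,18,1583,1.1,1
table1,2019,alcohol_drug_abuse,73,1583,4.6,1
table1,2019,cardiovascular_disease,62,1583,3.9,1
table1,2019,diabetes,77,1583,4.9,1
table1,2019,dyslipidemia,205,1583,13,1
table1,2019,hbv_hcv,136,1583,8.6,1
table1,2019,hypertension,399,1583,25.2,1
table1,2019,cci_0,1418,1583,89.6,1
table1,2019,cci_1,137,1583,8.7,1
table1,2019,cci_ge2,28,1583,1.8,1
table2,TAF-MTR,age_lt36,48,514,9.3,1
table2,TAF-MTR,age_36_55,332,514,64.6,1
table2,TAF-MTR,age_gt55,134,514,26.1,1
table2,TAF-MTR,male,378,514,73.5,1
table2,TAF-MTR,depression,39,514,7.6,1
table2,TAF-MTR,respiratory_disease,96,514,18.7,1
table2,TAF-MTR,renal_failure,7,514,1.4,1
table2,TAF-MTR,alcohol_drug_abuse,28,514,5.4,1
table2,TAF-MTR,cardiovascular_disease,20,514,3.9,1
table2,TAF-MTR,diabetes,20,514,3.9,1
table2,TAF-MTR,dyslipidemia,52,514,10.1,1
table2,TAF-MTR,hbv_hcv,49,514,9.5,1
table2,TAF-MTR,hypertension,117,514,22.8,1
table2,TAF-MTR,cancer,28,514,5.4,1
table2,TAF-MTR,cci_0,450,514,87.5,1
table2,TAF-MTR,cci_1,52,514,10.1,1
table2,TAF-MTR,cci_ge2,12,514,2.3,1
table2,TAF-STR,age_lt36,117,684,17.1,1
table2,TAF-STR,age_36_55,381,684,55.7,1
table2,TAF-STR,age_gt55,186,684,27.2,1
table2,TAF-STR,male,501,684,73.2,1
table2,TAF-STR,depression,49,684,7.2,1
table2,TAF-STR,respiratory_disease,105,684,15.4,1
table2,TAF-STR,alcohol_drug_abuse,22,684,3.2,1
table2,TAF-STR,cardiovascular_disease,16,684,2.3,1
table2,TAF-STR,diabetes,25,684,3.7,1
table2,TAF-STR,dyslipidemia,61,684,8.9,1
table2,TAF-STR,hbv_hcv,59,684,8.6,1
table2,TAF-STR,hypertension,117,684,17.1,1
table2,TAF-STR,cancer,16,684,2.3,1
table2,TAF-STR,cci_0,615,684,89.9,1
table2,TAF-STR,cci_1,56,684,8.2,1
table2,TAF-STR,cci_ge2,13,684,1.9,1
table2,naive,age_lt36,87,478,18.2,1
table2,naive,age_36_55,281,478,58.8,1
table2,naive,age_gt55,110,478,23,1
table2,naive,male,354,478,74.1,1
table2,naive,depression,35,478,7.3,1
table2,naive,respiratory_disease,76,478,15.9,1
table2,naive,renal_failure,4,478,0.8,1
table2,naive,alcohol_drug_abuse,11,478,2.3,1
table2,naive,cardiovascular_disease,10,478,2.1,1
table2,naive,diabetes,15,478,3.1,1
table2,naive,dyslipidemia,34,478,7.1,1
table2,naive,hbv_hcv,28,478,5.9,1
table2,naive,hypertension,80,478,16.7,1
table2,naive,cancer,11,478,2.3,1
table2,naive,cci_0,422,478,88.3,1
table2,naive,cci_1,45,478,9.4,1
table2,naive,cci_ge2,11,478,2.3,1
table2,TAF-switchers,age_lt36,78,720,10.8,1
table2,TAF-switchers,age_36_55,432,720,60,1
table2,TAF-switchers,age_gt55,210,720,29.2,1
table2,TAF-switchers,male,525,720,72.9,1
table2,TAF-switchers,depression,53,720,7.4,1
table2,TAF-switchers,respiratory_disease,125,720,17.4,1
table2,TAF-switchers,renal_failure,6,720,0.8,1
table2,TAF-switchers,alcohol_drug_abuse,39,720,5.4,1
table2,TAF-switchers,cardiovascular_disease,26,720,3.6,1
table2,TAF-switchers,diabetes,30,720,4.2,1
table2,TAF-switchers,dyslipidemia,79,720,11,1
table2,TAF-switchers,hbv_hcv,80,720,11.1,1
table2,TAF-switchers,hypertension,154,720,21.4,1
table2,TAF-switchers,cancer,33,720,4.6,1
table2,TAF-switchers,cci_0,643,720,89.3,1
table2,TAF-switchers,cci_1,63,720,8.8,1
table2,TAF-switchers,cci_ge2,14,720,1.9,1
table2,overall,age_lt36,165,1198,13.8,1
table2,overall,age_36_55,713,1198,59.5,1
table2,overall,age_gt55,320,1198,26.7,1
table2,overall,male,879,1198,73.4,1
table2,overall,depression,88,1198,7.3,1
table2,overall,respiratory_disease,201,1198,16.8,1
table2,overall,renal_failure,10,1198,0.8,1
table2,overall,alcohol_drug_abuse,50,1198,4.2,1
table2,overall,cardiovascular_disease,36,1198,3,1
table2,overall,diabetes,45,1198,3.8,1
table2,overall,dyslipidemia,113,1198,9.4,1
table2,overall,hbv_hcv,108,1198,9,1
table2,overall,hypertension,234,1198,19.5,1
table2,overall,cancer,44,1198,3.7,1
table2,overall,cci_0,1065,1198,88.9,1
table2,overall,cci_1,108,1198,9,1
table2,overall,cci_ge2,25,1198,2.1,1
text_subgroups,TAF cohort,mtr_share,514,1198,43,0
text_subgroups,TAF cohort,str_share,684,1198,57,0
text_subgroups,TAF cohort,naive_share,478,1198,40,0
text_subgroups,TAF cohort,switcher_share,720,1198,60,0
text_subgroups,ART cohort,male,1903,2658,71.6,1
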