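study_id,estimate_id,species,statistic_kind,value,se,ci_upper,t_value,df,n,year,parental_sex,offspring_sex,lab_method
s01,e01,Homo sapiens,slope_t,0.12,0.06,NA,2,96,100,2015,father,son,qPCR
s01,e02,Homo sapiens,correlation,0.31,NA,NA,NA,NA,52,2015,mother,daughter,qPCR
s02,e03,Homo sapiens,slope_ci,0.095,NA,0.124,NA,40,45,2019,father,unspecified,TRF_southern
s02,e04,Homo sapiens,slope_t,-0.05,0.04,NA,NA,120,124,2019,mother,unspecified,qPCR
s03,e05,Homo sapiens,correlation,0.18,NA,NA,NA,NA,80,2012,father,son,TRF_in_gel
s04,e06,Homo sapiens,estimate_ci,-0.087,NA,0.094,NA,30,35,2021,mother,unspecified,qPCR
s04,e07,Parus major,slope_t,0.21,0.08,NA,NA,25,29,2021,father,unspecified,qPCR
s05,e08,Parus major,correlation,-0.12,NA,NA,NA,NA,41,2008,mother,daughter,TRF_southern
s06,e09,Sterna hirundo,slope_t,0.09,0.05,NA,NA,60,64,2017,father,son,WGS
s06,e10,Sterna hirundo,slope_t,-0.04,0.03,NA,NA,58,62,2017,mother,son,qPCR
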