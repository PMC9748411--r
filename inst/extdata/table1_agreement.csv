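index_spec,intercept_fit,index_fit,mass_fit,time_fit,intercept_full,index_full,mass_full,time_full,r2_fit,r2_full,rmse,rmse_df,f,f_df1,f_df2,bias_kg,bias_pct,sd_kg,sd_pct,loa_lower_kg,loa_lower_pct,loa_upper_kg,loa_upper_pct,max_allowed_diff_kg,ccc,pearson,mape_median
SCL2/Rinf,-0.02,-0.11,1.01,-0.13,0.01,-0.10,1.00,-0.10,0.998,0.998,0.24,29,4495,3,29,0.06,0.18,0.25,0.79,-0.42,-8.59,0.54,9.13,0.73,0.998,0.998,3.28
CCL2/Rinf,-0.01,-0.11,1.01,-0.13,0.02,-0.14,1.02,-0.10,0.997,0.997,0.24,29,4475,3,29,0.06,0.28,0.25,1.25,-0.43,-8.73,0.54,9.46,0.73,0.998,0.998,3.38
SCL2/R0,-0.04,-0.44,1.12,-0.12,-0.02,-0.41,1.10,-0.08,0.998,0.997,0.19,29,6557,3,29,0.03,0.47,0.25,3.71,-0.45,-8.71,0.52,9.89,0.71,0.998,0.998,2.40
CCL2/R0,-0.03,-0.43,1.12,-0.12,-0.01,-0.39,1.10,-0.08,0.998,0.997,0.20,29,6485,3,29,0.03,0.61,0.25,5.02,-0.46,-8.82,0.52,10.24,0.71,0.998,0.998,3.59
SCL2/R50,-0.06,-0.32,1.09,-0.14,-0.03,-0.29,1.07,-0.11,0.999,0.998,0.19,29,6927,3,29,0.04,0.11,0.25,0.76,-0.46,-8.52,0.53,8.95,0.72,0.998,0.998,3.23
CCL2/R50,-0.04,-0.30,1.09,-0.14,-0.01,-0.28,1.07,-0.10,0.998,0.998,0.19,29,6792,3,29,0.03,0.22,0.25,1.73,-0.46,-9.06,0.53,9.72,0.71,0.998,0.998,3.42
SCL2/Ri,-0.00,-0.15,0.98,-0.13,0.00,-0.37,1.01,-0.13,0.997,0.997,0.27,29,3356,3,29,0.05,0.50,0.25,2.38,-0.43,-8.75,0.53,9.86,0.72,0.998,0.998,3.66
CCL2/Ri,-0.01,-0.14,0.98,-0.13,0.01,-0.36,1.01,-0.13,0.997,0.997,0.27,29,3372,3,29,0.05,0.48,0.25,2.33,-0.43,-8.80,0.54,9.97,0.72,0.998,0.998,3.65
body_mass,-0.06,NA,0.97,NA,0.11,NA,0.92,NA,0.996,0.994,0.02,13,3144,1,13,-0.21,6.35,0.36,11.43,-0.92,-4.93,0.50,9.40,1.18,0.991,0.998,23.59
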