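name,index_spec,intercept,index,body_mass,time,n_fit
prediction_scl_r50,SCL2/R50,-0.06,-0.32,1.09,-0.14,33
prediction_ccl_r50,CCL2/R50,-0.04,-0.30,1.09,-0.14,33
final_scl_r50,SCL2/R50,-0.03,-0.29,1.07,-0.11,49
final_ccl_r50,CCL2/R50,-0.01,-0.28,1.07,-0.10,49
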