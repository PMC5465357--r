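core_id,treatment,d15n_no3,d15n_no3_sd,cap17o_no3,cap17o_no3_sd,d15n_no2,d15n_no2_sd,cap17o_no2,cap17o_no2_sd,d15n_trn,d15n_trn_sd,d15n_n2o,d15n_n2o_sd,cap17o_n2o,cap17o_n2o_sd,sp_n2o,sp_n2o_sd
LN-mean,LN,14.0,1.0,^,^,6.6,2.2,^,^,11.9,1.1,13.7,1.7,^,^,7.2,3.4
LOLN-mean,LOLN,14.0,0.6,^,^,7.7,2.7,^,^,11.6,1.9,14.5,2.0,^,^,6.2,3.2
HN-mean,HN,4.6,0.2,14.7,0.7,-1.2,1.8,8.5,2.4,11.9,1.1,0.0,0.6,6.5,1.2,16.2,5.0
LOHN-mean,LOHN,5.3,0.5,14.7,0.6,-1.5,1.9,9.2,3.2,12.9,6.8,-0.7,1.1,5.4,1.3,12.9,2.5
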