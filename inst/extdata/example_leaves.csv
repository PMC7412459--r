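sample_id,srs,lba,L_D,a_D,b_D,L_B,a_B,b_B
LS-385,5.4,3.7,33.9,1.7,8.3,37.0,2.6,10.1
LS-101,5.4,3.9,23.1,8.1,5.2,50.3,-4.1,16.3
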