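"site_id","devil_activity","quoll_activity"
"full_s1",18.16,0.25
"full_s2",16.47,2.22
"full_s3",11.2,4.54
"full_s4",15.44,0.01
"full_s5",11.85,0.96
"full_s6",16.36,0.87
"full_s7",10.74,3.12
"reduced_s1",3.44,6.81
"reduced_s2",1.49,6.74
"reduced_s3",4.09,4.56
"reduced_s4",3.06,3.41
"reduced_s5",3.38,1.1
"simple_s1",0,0
"simple_s2",0,0
"simple_s3",0,0
"simple_s4",0,0
"simple_s5",0,0
"simple_s6",0,0
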