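group,id,outcome_name,pem,mean_A,sd_A,mean_post,sd_post,difference,dropout
PS,PS-1,sedentary_hours,68.6,10.3,1.6,10.1,1.3,0.2,FALSE
PS,PS-2,sedentary_hours,56.8,11.8,0.6,11.7,1.0,0.1,FALSE
PS,PS-3,sedentary_hours,60.8,10.1,0.9,10.0,1.0,0.1,FALSE
PS,PS-4,sedentary_hours,100.0,12.7,1.1,7.5,2.0,5.2,FALSE
PS,PS-5,sedentary_hours,73.1,11.4,0.9,10.0,2.0,1.4,FALSE
PS,PS-6,sedentary_hours,70.8,11.2,1.9,9.8,2.1,1.4,FALSE
PS,PS-7,sedentary_hours,87.0,12.4,0.7,11.1,1.3,1.3,FALSE
NPS,NPS-1,sedentary_hours,87.0,13.7,0.9,12.0,1.2,1.7,FALSE
NPS,NPS-2,sedentary_hours,83.2,12.0,2.3,10.6,1.6,1.4,FALSE
NPS,NPS-3,sedentary_hours,46.5,11.0,1.2,11.0,1.7,0.0,FALSE
NPS,NPS-4,sedentary_hours,64.8,11.0,1.1,10.9,1.0,0.1,FALSE
NPS,NPS-5,sedentary_hours,67.6,10.0,1.7,9.2,2.2,0.8,FALSE
NPS,NPS-6,sedentary_hours,22.2,10.9,1.4,11.0,0.9,-0.1,TRUE
NPS,NPS-7,sedentary_hours,69.9,10.4,1.7,9.2,2.2,1.2,FALSE
PS,PS-1,fragmentation_index,64.7,3.9,1.1,4.9,1.9,1.0,FALSE
PS,PS-2,fragmentation_index,76.3,2.8,0.4,3.4,0.7,0.6,FALSE
PS,PS-3,fragmentation_index,58.8,7.2,1.6,7.5,1.8,0.3,FALSE
PS,PS-4,fragmentation_index,87.0,4.8,1.1,6.8,2.1,2.0,FALSE
PS,PS-5,fragmentation_index,69.7,2.6,0.7,3.5,1.9,0.9,FALSE
PS,PS-6,fragmentation_index,89.6,2.8,1.3,4.7,1.8,1.9,FALSE
PS,PS-7,fragmentation_index,87.0,3.5,1.1,4.2,0.8,0.7,FALSE
NPS,NPS-1,fragmentation_index,46.0,4.1,0.7,4.1,1.1,0.0,FALSE
NPS,NPS-2,fragmentation_index,71.4,2.3,0.5,3.3,1.1,1.0,FALSE
NPS,NPS-3,fragmentation_index,52.5,4.3,1.0,4.4,1.5,0.1,FALSE
NPS,NPS-4,fragmentation_index,23.8,4.0,1.0,3.3,0.7,-0.7,FALSE
NPS,NPS-5,fragmentation_index,54.3,5.6,0.9,5.9,2.2,0.3,FALSE
NPS,NPS-6,fragmentation_index,58.3,6.0,1.8,5.7,1.2,-0.3,TRUE
NPS,NPS-7,fragmentation_index,83.5,3.4,0.3,4.1,0.8,0.7,FALSE
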