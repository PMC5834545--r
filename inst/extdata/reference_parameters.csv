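flux_id,gamma,f,enzyme_id,enzyme_activity
v0->3,9566518799.45,1.15,PI3KII,1.2e-15
v0->4,7.54221666098e+15,0.355673647546,PI4K,2e-15
v0->5,6.19788376889e+14,0.462771482844,PIKfyve,6e-16
v0->45,3.21396140089e+17,0.16015268799,PI4K_PIP5KI_DVL,3e-16
v4->45,2.28979900143e+17,0.1,PIP5KI,8e-16
v4->34,4.83265066895e+14,0.540067275116,PI3KII,1.2e-15
v5->45,1.52457936408e+16,0.586698323982,PIP5KII,5e-16
v3->35,7.78292264957e+13,1.15,PIKfyve,6e-16
v45->345,1.94897653834e+14,0.3,PI3KI,2.67126569491e-15
v3->0,2.0878119429e+15,0.3,MTMR,9e-16
v4->0,3.18376031688e+14,0.868654635024,SAC1,2.5e-15
v5->0,3.65658191741e+12,1,PI5P_PASE,5e-16
v45->0,3.83365577441e+14,0.681434684427,SYNJ,1.1e-15
v45->4,2.74055366941e+13,1.06709040327,SIOSS,1.5e-15
v45->5,986828569492,1.15,SYNJ_TMEM55,7e-16
v345->45,3.96042028011e+14,1,PTEN,9.27847971371e-16
v345->34,100000000000,0.9982,SHIP,1e-15
v34->4,5.50294329798e+14,1,PTEN,9.27847971371e-16
v34->3,8.98647980474e+12,1,INPP4,4e-16
v35->5,2.30506357766e+15,0.76712328628,MTMR,9e-16
v35->3,1.02313534815e+15,1,FIG4,3e-16
v->0,22485.114256,,,
v->4,923.832446178,,,
v->3,36.9532978471,,,
v0->,0.045,1,,
v3->,0.045,1,,
v4->,0.045,1,,
v5->,0.045,1,,
v34->,0.045,1,,
v35->,0.045,1,,
v45->,0.045,1,,
v345->,0.045,1,,
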