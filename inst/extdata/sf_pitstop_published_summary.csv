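block,stratum,n_interventions,pre_mean,pre_sd,post_mean,post_sd,delta_printed,p_printed
intervention_type,Installation of New Restroom,13,49.18,48.45,36.71,27.17,-12.47,0.0002
intervention_type,Provision of Attendants,15,22.75,26.56,20.87,16.95,-1.88,0.2296
intervention_type,Expansion of Service Hours,3,34.45,16.92,46.45,29.45,12.00,0.0016
neighborhood,Tenderloin,11,68.01,45.18,50.40,21.89,-17.60,0.0002
neighborhood,Mission,5,26.98,12.71,28.24,11.57,1.25,0.4068
neighborhood,South of Market (SoMa),4,37.42,13.92,39.38,21.55,1.95,0.4406
neighborhood,Castro/Upper Market,4,8.99,5.30,12.08,6.19,3.09,0.0004
neighborhood,Golden Gate Park,2,0.69,1.04,0.85,1.23,0.15,0.5561
neighborhood,Haight Ashbury,1,1.08,1.38,1.85,1.91,0.77,0.1242
neighborhood,Bayview Hunters Point,1,2.50,1.48,2.35,1.72,-0.15,0.7953
neighborhood,Sunset Parkside,1,0.27,0.53,0.65,0.75,0.38,0.0606
neighborhood,North Beach,1,6.65,3.67,15.19,4.89,8.54,0.0002
neighborhood,Financial District/South Beach,1,3.35,2.42,6.50,4.31,3.15,0.0030
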