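category,arm,mean,variance,availability
utility,control,0.447,0.01,both
utility,intervention,0.654,0.002,both
outpatient_appointment,control,5.75,1.00,both
outpatient_appointment,intervention,5.16,0.44,both
gp_appointment,control,1.56,0.25,both
gp_appointment,intervention,1.00,0.10,both
other_services_control,control,1.75,0.39,control_only
other_services_intervention,intervention,0.32,0.03,intervention_only
counsellor,control,0.94,0.34,control_only
physiotherapist,control,1.81,1.24,control_only
outpatient_hospice,intervention,2.05,0.07,intervention_only
dtu_attendance,intervention,5.20,1.05,intervention_only
hospice_physiotherapy,intervention,3.55,0.97,intervention_only
other_hospice,intervention,1.50,0.21,intervention_only
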