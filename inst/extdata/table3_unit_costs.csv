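category,unit_cost_gbp,unit_description,source
outpatient_appointment,152.00,outpatient attendance,national
gp_appointment,32.00,per 12 minute consultation,national
counsellor,44.00,per hour client contact,national
physiotherapist,18.50,30 minute consultation,national
outpatient_hospice,104.40,per hospice outpatient appointment,hospice
dtu_attendance,139.80,cost per DTU attendance,hospice
hospice_physiotherapy,18.50,30 minute consultation,national
other_hospice,37.27,weighted average of hospice services used by the intervention group,national
other_services_control,66.09,weighted average of other service use costs (control group),national
other_services_intervention,70.42,weighted average of other service use costs (intervention group),national
inpatient_admission,225.00,NHS cost per bed day,national
gp_home_visit,115.00,25 minute home visit,national
practice_nurse,10.00,per consultation,national
district_nurse_home,68.00,per hour home visit,national
palliative_nurse_home,68.00,per hour home visit,national
occupational_therapist,51.33,40 minute consultation,national
psychologist,81.00,per hour client contact,national
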