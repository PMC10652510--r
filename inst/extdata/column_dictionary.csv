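"name","table","type","units","levels","missing"
"id","record","character","","","empty cell"
"sex","record","character","","male|female","empty cell"
"age","record","integer","years","","empty cell"
"witnessed","record","logical","","","empty cell"
"bystander_cpr","record","logical","","","empty cell"
"initial_rhythm","record","character","","VF_VT|PEA|asystole","empty cell"
"bystander_aed","record","logical","","","empty cell"
"physician_staffed","record","logical","","","empty cell"
"shock_by_paramedic","record","logical","","","empty cell"
"advanced_airway","record","character","","intubation|SGA|none","empty cell"
"prehosp_adrenaline_n","record","integer","","","empty cell"
"prehosp_rosc","record","logical","","","empty cell"
"call_to_hospital_min","record","integer","minutes from emergency call","","empty cell"
"hospital_id","record","character","","","empty cell"
"arrest_cause","record","character","","medical|external","empty cell"
"resuscitation_attempted","record","logical","","","empty cell"
"arrest_on_ems_contact","record","logical","","","empty cell"
"rosc_before_arrival_sustained","record","logical","","","empty cell"
"defib_minutes","timeline","minutes","minutes from hospital arrival","","empty cell"
"intubation_minute","timeline","integer","minutes from hospital arrival","","empty cell"
"adrenaline_minutes","timeline","minutes","minutes from hospital arrival","","empty cell"
"ecpr_minute","timeline","integer","minutes from hospital arrival","","empty cell"
"disposition","timeline","character","","ROSC|death|ECPR|censored","empty cell"
"disposition_minute","timeline","integer","minutes from hospital arrival","","empty cell"
"survival_30d","timeline","logical","","","empty cell"
"cpc_1_2","timeline","logical","","","empty cell"
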