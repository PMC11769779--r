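{"patient_id":"EX001","age_years":24,"sex_assigned_at_birth":"female","administrative_sex":"female","problem_list":[],"medical_history":[],"chief_complaints":["chest pain"],"vitals":[{"time":"2023-01-20T13:10:00Z","kind":"HR","value":78},{"time":"2023-01-20T13:40:00Z","kind":"HR","value":82},{"time":"2023-01-20T13:10:00Z","kind":"RR","value":16},{"time":"2023-01-20T13:40:00Z","kind":"RR","value":17},{"time":"2023-01-20T13:10:00Z","kind":"SBP","value":118},{"time":"2023-01-20T13:40:00Z","kind":"SBP","value":121},{"time":"2023-01-20T13:10:00Z","kind":"TEMP","value":36.8},{"time":"2023-01-20T13:40:00Z","kind":"TEMP","value":36.9},{"time":"2023-01-20T13:10:00Z","kind":"SPO2","value":98},{"time":"2023-01-20T13:40:00Z","kind":"SPO2","value":97}],"oxygen_records":[{"time":"2023-01-20T13:10:00Z","device":"room_air","flow_lpm":0}],"gcs_records":[{"time":"2023-01-20T13:15:00Z","value":15}],"home_o2_lpm":0,"prior_encounter_count":2,"trigger_time":"2023-01-20T14:05:00Z"}
{"patient_id":"EX002","age_years":67,"sex_assigned_at_birth":"male","administrative_sex":"male","problem_list":[{"snomed_code":"93880001","status":"active","recorded_time":"2022-03-02T09:00:00Z"}],"medical_history":[{"snomed_code":"42343007","status":"history","recorded_time":"2019-11-12T09:00:00Z"}],"chief_complaints":["dyspnea"],"vitals":[{"time":"2023-01-20T13:00:00Z","kind":"HR","value":104},{"time":"2023-01-20T13:50:00Z","kind":"HR","value":115},{"time":"2023-01-20T13:00:00Z","kind":"RR","value":22},{"time":"2023-01-20T13:50:00Z","kind":"RR","value":24},{"time":"2023-01-20T13:00:00Z","kind":"SBP","value":112},{"time":"2023-01-20T13:50:00Z","kind":"SBP","value":104},{"time":"2023-01-20T13:00:00Z","kind":"TEMP","value":36.4},{"time":"2023-01-20T13:50:00Z","kind":"TEMP","value":36.2},{"time":"2023-01-20T13:00:00Z","kind":"SPO2","value":91},{"time":"2023-01-20T13:50:00Z","kind":"SPO2","value":88}],"oxygen_records":[{"time":"2023-01-20T13:00:00Z","device":"room_air","flow_lpm":0},{"time":"2023-01-20T13:55:00Z","device":"nasal_cannula","flow_lpm":4}],"gcs_records":[{"time":"2023-01-20T13:05:00Z","value":15}],"home_o2_lpm":0,"prior_encounter_count":11,"trigger_time":"2023-01-20T14:05:00Z"}
{"patient_id":"EX003","age_years":81,"sex_assigned_at_birth":"female","administrative_sex":"female","problem_list":[],"medical_history":[{"snomed_code":"13645005","status":"history","recorded_time":"2016-05-30T09:00:00Z"}],"chief_complaints":["altered mental status"],"vitals":[{"time":"2023-01-20T13:30:00Z","kind":"HR","value":92},{"time":"2023-01-20T13:30:00Z","kind":"RR","value":20},{"time":"2023-01-20T13:30:00Z","kind":"SBP","value":135},{"time":"2023-01-20T13:30:00Z","kind":"TEMP","value":36.5},{"time":"2023-01-20T13:30:00Z","kind":"SPO2","value":94}],"oxygen_records":[],"gcs_records":[{"time":"2023-01-20T13:35:00Z","value":13}],"home_o2_lpm":2,"prior_encounter_count":0,"trigger_time":"2023-01-20T14:05:00Z"}
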