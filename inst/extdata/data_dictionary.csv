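column,level,type,units,description
diarrhea,child,binary,,1 if the child had diarrhea within the two weeks before interview
age,child,integer,months,child age; 0-59 (all children under five)
household_id,household,id,,household identifier; unique within the survey
cluster_id,cluster,id,,survey cluster identifier
urban,cluster,binary,,1 if the cluster is urban
wealth_high,household,binary,,1 if household wealth is in the top two quintiles
edu_secondary,household,binary,,1 if the mother has secondary education or higher
improved_sanitation,household,binary,,1 if the sanitation facility is improved under the WHO/JMP mapping
improved_water,household,binary,,1 if the drinking-water source is improved under the WHO/JMP mapping
precip_lag_z,cluster,numeric,z-score,long-term mean precipitation of the month before the survey month; standardized over the analysis sample
precip_change,cluster,numeric,z-score,survey-month minus previous-month long-term precipitation; standardized
temp_lag_z,cluster,numeric,z-score,long-term mean temperature of the month before the survey month; standardized
temp_change,cluster,numeric,z-score,survey-month minus previous-month long-term temperature; standardized
human_index,cluster,numeric,percent,upstream human-activity water-source index averaged in the 10 km window
tree_index,cluster,numeric,percent,upstream tree-cover water-source index averaged in the 10 km window
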