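quantity,count
total_ish_incl_er_deaths,36936
er_deaths,1418
posthosp_death_excluded,410
nonfatal_ish,35518
suicide_deaths,13416
total_study_cases,48934
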