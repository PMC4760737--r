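# Example gutabm configuration: desk-scale toxin-antitoxin community
# with a 3-day once-daily antibiotic course. Omitted keys keep their
# defaults; see ?gut_params for the full schema.

gut_length_L = 150000
gut_width_D = 30000
tick_hours = 0.02

feedbacks_enabled = FB1, FB3
fb1_toxin_percentage = 50

k_ant_intake = 300
ant_gavages_per_day = 1
ant_course_days = 3
ant_course_start = 300
ant_gavage_duration = 1

mutation_rate_scale_alpha = 1
retardation_constant_Rc = 1

rng_seed = 1
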