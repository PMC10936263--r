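respondent,comfort,adjustability,ease_of_use,hinders_job,recommend
R01,0.6,0.7,0.5,0.1,0.8
R02,0.4,0.5,0.6,-0.2,0.7
R03,0.7,0.6,0.4,0.0,0.9
R04,0.3,0.4,0.5,-0.1,0.6
R05,0.5,0.8,0.7,0.2,0.8
R06,0.6,0.5,0.3,-0.3,0.7
R07,0.2,0.6,0.6,0.0,0.5
R08,0.8,0.7,0.5,0.1,0.9
R09,0.4,0.3,0.4,-0.2,0.6
R10,0.5,0.6,0.6,0.0,0.8
R11,0.7,0.5,0.5,-0.1,0.7
R12,0.3,0.7,0.4,0.2,0.6
R13,0.6,0.6,0.7,0.0,0.9
R14,0.5,0.4,0.5,-0.2,0.7
R15,0.4,0.6,0.6,0.1,0.8
R16,0.6,0.5,0.4,0.0,0.7
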