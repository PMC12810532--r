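stratum,engine_grade,adjudicated_grade,n
sas,moderate_to_severe,moderate_to_severe,87
sas,severe,severe,103
sas,severe,moderate,8
sas,critical,none,2
below,mild,mild,86
below,mild,not_specified,42
below,mild_to_moderate,mild_to_moderate,21
below,moderate,moderate,33
below,moderate,not_specified,18
no_as,none,none,200
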