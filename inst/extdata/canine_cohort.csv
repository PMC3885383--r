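subject_id,duration_days,n_seizures,n_lead
002,197,27,27
004,330,15,8
007,451,83,18
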