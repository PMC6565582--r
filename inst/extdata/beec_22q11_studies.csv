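label,n_cases,case_carriers,n_controls,control_carriers
pooled_published_beec_cohorts,422,11,1219,1
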