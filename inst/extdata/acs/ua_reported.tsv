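# Literature-reported biomarker miRNAs for unstable angina (UA).
mirna	role
miR-132	diagnostic
miR-150	diagnostic
miR-186	diagnostic
miR-106b	diagnostic
miR-25	diagnostic
miR-590-5p	diagnostic
miR-126	diagnostic
miR-133a	both
miR-208b	both
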