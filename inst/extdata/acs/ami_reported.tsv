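# Literature-reported biomarker miRNAs for acute myocardial infarction (AMI).
mirna	role
miR-155	prognostic
miR-380*	prognostic
miR-16	prognostic
miR-27a	prognostic
miR-101	prognostic
miR-150	prognostic
miR-208b	both
miR-133a	both
miR-34a	diagnostic
miR-126	diagnostic
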