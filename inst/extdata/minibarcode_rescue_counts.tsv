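genus	n_tested	pcr_positive	sequence_positive
Cortinarius	30	30	24
Russula	30	30	27
Mycena	30	27	4
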