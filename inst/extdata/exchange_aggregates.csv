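subject,experiment,n_correct_exchanges,n_incorrect_exchanges,n_correct_behaviors,n_complete_sequences
Manda,exp2,6,0,6,6
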