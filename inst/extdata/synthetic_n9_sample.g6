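H[YWFCG
HoIP?iC
HrVbHpB
HT@oRR\
HoWgoEL
HaxyEHH
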