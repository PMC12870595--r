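disease_id	term_id
DIS:0001	SP:0000004
DIS:0002	SP:0000005
DIS:0003	SP:0000006
DIS:0004	SP:0000003
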