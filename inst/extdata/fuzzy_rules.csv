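# 5x5 Mamdani rule base mapping (model-following error e, error rate de) to the
# adaptation gain m. Rows: e label; columns: de label. Transcribed verbatim from the
# source rule table, including its deliberate asymmetry (the PM/PB rows are not mirror
# images of the NM/NB rows).
e,NB,NM,ZE,PM,PB
NB,NB,NB,NB,NM,ZE
NM,NB,NB,NM,ZE,PM
ZE,NB,NM,ZE,PM,PB
PM,PM,PM,PM,PB,PB
PB,PM,PM,PB,PB,PB
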