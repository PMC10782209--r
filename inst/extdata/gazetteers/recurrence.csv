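term,rule_id,attribute,value
recurrent,rec_recurrent,recurrent,true
recurrence,rec_recurrence,recurrent,true
previously excised,rec_prev_excised,recurrent,true
re-presentation,rec_represent,recurrent,true
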