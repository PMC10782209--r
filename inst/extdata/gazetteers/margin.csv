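term,rule_id,attribute,value
completely excised,mar_clear_both,margin,clear_both
complete excision,mar_clear_both2,margin,clear_both
excision is complete,mar_clear_both3,margin,clear_both
excision appears complete,mar_clear_both4,margin,clear_both
clear of the margins,mar_clear_both5,margin,clear_both
clear of margins,mar_clear_both6,margin,clear_both
incompletely excised,mar_inv_lex,margin,involved_lex
incomplete excision,mar_inv_lex2,margin,involved_lex
extends to the peripheral margin,mar_inv_p1,margin,involved_peripheral
reaches the peripheral margin,mar_inv_p2,margin,involved_peripheral
involves the peripheral margin,mar_inv_p3,margin,involved_peripheral
involving the peripheral margin,mar_inv_p4,margin,involved_peripheral
extends to the deep margin,mar_inv_d1,margin,involved_deep
reaches the deep margin,mar_inv_d2,margin,involved_deep
involves the deep margin,mar_inv_d3,margin,involved_deep
involving the deep margin,mar_inv_d4,margin,involved_deep
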