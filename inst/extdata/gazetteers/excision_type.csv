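term,rule_id,attribute,value
ellipse,exc_ellipse,excision_type,excision
excision,exc_excision,excision_type,excision
wide local excision,exc_wle,excision_type,excision
excised,exc_excised,excision_type,excision
punch biopsy,exc_punch,excision_type,punch_biopsy
punch,exc_punch_short,excision_type,punch_biopsy
incision biopsy,exc_incision,excision_type,incision_biopsy
incisional biopsy,exc_incisional,excision_type,incision_biopsy
shave biopsy,exc_shave,excision_type,shave_biopsy
shave,exc_shave_short,excision_type,shave_biopsy
curettage,exc_curettage,excision_type,curettage
curettings,exc_curettings,excision_type,curettage
curetted,exc_curetted,excision_type,curettage
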