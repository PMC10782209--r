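term,rule_id,attribute,value
no evidence of,neg_no_evidence,negation,pre
no residual,neg_no_residual,negation,pre
negative for,neg_negative_for,negation,pre
not seen,neg_not_seen,negation,pre
free of,neg_free_of,negation,pre
no,neg_no,negation,pre
without,neg_without,negation,pre
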