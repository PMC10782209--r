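term,rule_id,attribute,value
basal cell carcinoma,dx_bcc,diagnosis_class,bcc
bcc,dx_bcc_abbr,diagnosis_class,bcc
nodular basal cell carcinoma,dx_bcc_nodular,diagnosis_class,bcc/nodular
nodular bcc,dx_bcc_nodular_abbr,diagnosis_class,bcc/nodular
superficial basal cell carcinoma,dx_bcc_superficial,diagnosis_class,bcc/superficial
superficial bcc,dx_bcc_superficial_abbr,diagnosis_class,bcc/superficial
infiltrative basal cell carcinoma,dx_bcc_infiltrative,diagnosis_class,bcc/infiltrative
infiltrative bcc,dx_bcc_infiltrative_abbr,diagnosis_class,bcc/infiltrative
micronodular basal cell carcinoma,dx_bcc_micronodular,diagnosis_class,bcc/micronodular
micronodular bcc,dx_bcc_micronodular_abbr,diagnosis_class,bcc/micronodular
morphoeic basal cell carcinoma,dx_bcc_morphoeic,diagnosis_class,bcc/morphoeic
morphoeic bcc,dx_bcc_morphoeic_abbr,diagnosis_class,bcc/morphoeic
seborrhoeic keratosis,dx_sk,diagnosis_class,benign
seborrheic keratosis,dx_sk_us,diagnosis_class,benign
dermatofibroma,dx_df,diagnosis_class,benign
intradermal naevus,dx_idn,diagnosis_class,benign
compound naevus,dx_cn,diagnosis_class,benign
benign lichenoid keratosis,dx_blk,diagnosis_class,benign
epidermal cyst,dx_cyst,diagnosis_class,benign
viral wart,dx_wart,diagnosis_class,benign
squamous cell carcinoma,dx_scc,diagnosis_class,other_cancer
malignant melanoma,dx_mm,diagnosis_class,other_cancer
melanoma,dx_mel,diagnosis_class,other_cancer
merkel cell carcinoma,dx_mcc,diagnosis_class,other_cancer
squamous cell carcinoma in situ,dx_scc_insitu,diagnosis_class,other_in_situ
bowen disease,dx_bowen,diagnosis_class,other_in_situ
bowen's disease,dx_bowens,diagnosis_class,other_in_situ
melanoma in situ,dx_mis,diagnosis_class,other_in_situ
lentigo maligna,dx_lm,diagnosis_class,other_in_situ
keratoacanthoma,dx_ka,diagnosis_class,other_intermediate
atypical fibroxanthoma,dx_afx,diagnosis_class,other_intermediate
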