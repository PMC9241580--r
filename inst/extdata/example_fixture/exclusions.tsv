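variant_id	reason
rs4713555	associated with confounders (thyroid disease, type 1 diabetes)
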