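gene	rule
TP53	tumor_suppressor_inactivating
EGFR	driver_sensitive
KRAS	driver_high_frequency
BRAF	driver_sensitive
PTEN	tumor_suppressor_inactivating
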