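# ontofuse demo edit script: one op per line, fields tab-separated
# drop immortalised cell-line classes, then precondition all labels
deselect	immortalized
normalize_labels	-, /	cell, cells, human
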