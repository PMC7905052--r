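# ontofuse demo configuration (key = value; lists comma-separated)
W = 4
theta_N = 0.85
theta_T = 0.7
theta_LN = 0.7
metric = cosine
use_synonyms = true
stop_words = cell, cells, human
strip_chars = -, /
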