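# Shared constants; this file loads before all others.

# base alphabet used throughout; integer codes are 0-based (A=0 ... T=3)
BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# the six pyrimidine-represented substitution types
SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
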