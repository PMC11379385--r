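# package-wide constants (loaded first)
RNA_BASES <- c("A", "C", "G", "U")
DINUCS <- as.vector(outer(RNA_BASES, RNA_BASES, paste0))
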