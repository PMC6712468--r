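# data.table column references used non-standardly
utils::globalVariables(c("mapq", "baseq", "count", "role", "allele",
                         ".BY", ".SD", ".N"))
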