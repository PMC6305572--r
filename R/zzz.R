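# required so data.table's `[` dispatch works from this package's namespace
.datatable.aware <- TRUE
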