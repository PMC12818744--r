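# data.table is used through :: but the package must still be flagged as
# data.table-aware for [] dispatch on its tables.
.datatable.aware <- TRUE
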