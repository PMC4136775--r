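# data.table is used via :: throughout; declare awareness so [.data.table
# dispatch works when the package is not attached
.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "adjusted_p", "boundary3", "boundary5", "carriers",
  "combined_frequency", "distance", "features", "fusion_id", "gene3",
  "gene5", "k3", "k5", "novel", "orientation", "raw_p", "role",
  "significant", "split_reads", "testable", "tested_m", "unknown_gene",
  "variant_id", "weight", "pos", "frequency", "expected_in_catalog"))
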