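# Small cohort builders shared across test files.

under_effects <- function(k, effect_size = 5, sex_scope = "both",
                          carrier_count = 1, stride = 4, direction = "under") {
  lapply(seq_len(k), function(i) {
    planted_effect(gene_id = sprintf("G%04d", i * stride),
                   effect_size = effect_size,
                   direction = if (length(direction) > 1) direction[1 + i %% 2]
                   else direction,
                   sex_scope = sex_scope, carrier_count = carrier_count)
  })
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_female = 30, n_male = 30, n_genes = 40, n_tissues = 4)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# carriers of a truth row
truth_carriers <- function(bundle, i) {
  vid <- bundle$truth$variant_id[i]
  bundle$variants$carriers[[match(vid, bundle$variants$variant_id)]]
}
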