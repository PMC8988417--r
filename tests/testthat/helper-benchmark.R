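# Shared large-sample benchmark objects, computed once per test session on
# first use: derivation and validation cohorts from the default mechanism
# (no censoring) and the Cox model fitted on the derivation data.

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (!exists("fix", envir = .benchmark_cache)) {
    derivation <- generate_cohort(table1_config(1e6, "none", seed = 20260101))
    validation <- generate_cohort(table1_config(1e6, "none", seed = 20260102))
    model <- fit_cox(derivation, "x")
    .benchmark_cache$fix <- list(derivation = derivation,
                                 validation = validation, model = model)
  }
  .benchmark_cache$fix
}
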