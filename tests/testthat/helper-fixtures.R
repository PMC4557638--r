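# Shared fixtures. Everything is generated in code; a small schema keeps the
# unit-test fits fast (3 years, 3 regions instead of 12 and 9).

small_schema <- function() {
  default_schema(years = 2004:2006, regions = c("west", "center", "east"))
}

small_config <- function(n = 8000, masking = masking_uniform(0.15),
                         seed = 1L) {
  default_russia_like_config(n_records = n, masking = masking,
                             schema = small_schema(), seed = seed)
}

# memoized male fit on a small dataset, shared across tests
.fixture_env <- new.env(parent = emptyenv())

fixture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    g <- generate_microdata(small_config(n = 12000, seed = 7))
    known <- g$records[g$records$cause_class %in% CAUSE_LEVELS &
                         g$records$sex == "male", ]
    euis <- g$records[g$records$cause_class == "EUI" &
                        g$records$sex == "male", ]
    .fixture_env$fit <- list(
      gen = g, known = known, euis = euis,
      model = suppressWarnings(fit_mlogit(known))
    )
  }
  .fixture_env$fit
}

# balanced-mix config (class weights ~1) reusing the default covariate world
balanced_config <- function(n, schema = default_schema(), seed = 1L,
                            masking = masking_uniform(0)) {
  base <- default_russia_like_config(n_records = n, schema = schema,
                                     seed = seed)
  generator_config(n_records = n, cause_mix = rep(1 / 3, 3),
                   sex_by_cause = base$sex_by_cause,
                   covariates = base$covariates,
                   masking = masking, schema = schema, seed = seed)
}

expect_prob_rows <- function(p, tol = 1e-9) {
  expect_true(all(p >= -tol & p <= 1 + tol))
  expect_lt(max(abs(rowSums(p) - 1)), tol)
}
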