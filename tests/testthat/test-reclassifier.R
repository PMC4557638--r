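test_that("assign_cause thresholds the maximum ECP", {
  expect_identical(assign_cause(c(0.8, 0.1, 0.1), 0.75)[1], "NTA")
  expect_identical(assign_cause(c(0.5, 0.3, 0.2), 0.75)[1], NA_character_)
  expect_identical(assign_cause(c(0.34, 0.33, 0.33), 0)[1], "NTA")
  expect_identical(assign_cause(c(0.2, 0.5, 0.3), 0.5)[1], "SUI")  # >= not >
  # ties broken by fixed cause order and counted
  a <- assign_cause(rbind(c(0.4, 0.4, 0.2), c(0.3, 0.35, 0.35)), 0)
  expect_identical(as.vector(a), c("NTA", "SUI"))
  expect_identical(attr(a, "ties"), 2L)
  expect_error(assign_cause(c(0.8, 0.1, 0.1), 1.5), "ecp0")
})

test_that("class matrix counts match behaviour at the threshold extremes", {
  fx <- fixture_fit()
  # a perfect classifier: hand-built ECPs equal to the actual cause
  rec <- fx$known[1:300, ]
  rec$cause_class <- factor(rep(CAUSE_LEVELS, each = 100),
                            levels = OBSERVED_CAUSE_LEVELS)
  ecp_perfect <- diag(3)[rep(1:3, each = 100), ]
  cm <- build_class_matrix(fx$model, rec, 0, ecp = ecp_perfect)
  expect_equal(unname(cm$d), diag(100, 3))
  expect_equal(unname(cm$D_P), rep(100, 3))
  expect_equal(unname(relative_error(cm)), c(0, 0, 0))
  expect_equal(agreement_share(cm)$overall, 1)

  # ecp0 = 1 with continuous probabilities leaves everything unclassified
  cm1 <- build_class_matrix(fx$model, fx$known, 1)
  expect_identical(sum(cm1$d), 0L)
  expect_identical(cm1$unclassified, nrow(fx$known))
})

test_that("class matrix equals the naive per-record counting oracle", {
  fx <- fixture_fit()
  rec <- fx$known[1:1000, ]
  ecp <- predict_ecp(fx$model, rec)
  actual <- as.character(rec$cause_class)
  for (e0 in c(0, 0.5, 0.75, 0.9)) {
    cm <- build_class_matrix(fx$model, rec, e0, ecp = ecp)
    d_oracle <- matrix(0L, 3, 3); unc <- 0L
    for (n in seq_len(nrow(rec))) {          # naive loop, no shared code
      i <- which.max(ecp[n, ])
      if (ecp[n, i] >= e0) {
        j <- match(actual[n], CAUSE_LEVELS)
        d_oracle[i, j] <- d_oracle[i, j] + 1L
      } else unc <- unc + 1L
    }
    expect_identical(unname(cm$d) + 0L, d_oracle)
    expect_identical(cm$unclassified, unc)
    expect_identical(unname(cm$D_P), rowSums(d_oracle))
    expect_identical(unname(cm$D_A), colSums(d_oracle))
  }
})

test_that("relative error and agreement follow their formulas", {
  mk <- function(d) {
    structure(list(d = d, ecp0 = 0, unclassified = 0L, n_scored = sum(d),
                   D_P = rowSums(d), D_A = colSums(d)),
              class = "eui_class_matrix")
  }
  d <- rbind(c(90, 0, 0), c(10, 100, 0), c(0, 0, 100))
  expect_equal(unname(relative_error(mk(d))), c(-0.10, 0.10, 0))
  # identity: actual-weighted errors cancel when nothing is unclassified
  expect_equal(sum(colSums(d) * relative_error(mk(d))), 0)

  d2 <- rbind(c(90, 5, 5), c(10, 80, 10), c(20, 10, 70))
  ag <- agreement_share(mk(d2))
  expect_equal(ag$overall, 240 / 300)
  expect_equal(unname(ag$by_actual), c(90 / 120, 80 / 95, 70 / 85))
  expect_true(all(ag$by_actual >= 0 & ag$by_actual <= 1))
})

test_that("misclassification matrix rows are conditional distributions", {
  mk <- function(d) {
    structure(list(d = d, ecp0 = 0, unclassified = 0L, n_scored = sum(d),
                   D_P = rowSums(d), D_A = colSums(d)),
              class = "eui_class_matrix")
  }
  expect_equal(unname(build_misclass_matrix(mk(diag(50, 3)))$P), diag(3))
  d2 <- rbind(c(90, 5, 5), c(10, 80, 10), c(20, 10, 70))
  mm <- build_misclass_matrix(mk(d2))
  expect_equal(unname(mm$P[1, ]), c(0.9, 0.05, 0.05))
  expect_equal(unname(rowSums(mm$P)), rep(1, 3))
  # reconstruction identity sum_i P_ij D_i^P = D_j^A on fuzzed matrices
  set.seed(77)
  for (r in 1:20) {
    d <- matrix(rpois(9, 40), 3, 3)
    cm <- mk(d)
    mm <- build_misclass_matrix(cm)
    expect_equal(as.numeric(crossprod(mm$P, cm$D_P)), unname(cm$D_A))
  }
  # zero predicted marginal is flagged, not zeroed
  d0 <- rbind(c(0, 0, 0), c(10, 80, 10), c(20, 10, 70))
  mm0 <- build_misclass_matrix(mk(d0))
  expect_true(mm0$undefined_rows[1])
  expect_error(population_adjust(mm0, c(5, 1, 1)), "undefined")
  expect_equal(unname(population_adjust(mm0, c(0, 10, 10))[1]),
               0.1 * 10 + 0.2 * 10)
})

test_that("population adjustment redistributes and conserves mass", {
  mk_mm <- function(P) structure(list(P = P, undefined_rows = rep(FALSE, 3)),
                                 class = "eui_misclass_matrix")
  expect_equal(unname(population_adjust(mk_mm(diag(3)), c(7, 5, 3))),
               c(7, 5, 3))
  P <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.2, 0.1, 0.7))
  expect_equal(unname(population_adjust(mk_mm(P), c(100, 50, 50))),
               c(105, 50, 45))
  set.seed(4)
  for (r in 1:20) {
    P <- matrix(rgamma(9, 1), 3, 3); P <- P / rowSums(P)
    U <- rpois(3, 100)
    expect_equal(sum(population_adjust(mk_mm(P), U)), sum(U))
  }
})

test_that("EUI reclassification counts are complete and monotone", {
  fx <- fixture_fit()
  ecp <- predict_ecp(fx$model, fx$euis)
  rc0 <- reclassify_euis(fx$model, fx$euis, 0, ecp = ecp)
  expect_identical(rc0$unclassified, 0L)
  expect_equal(sum(rc0$U), nrow(fx$euis))
  prev <- -1L
  for (e0 in DEFAULT_ECP_GRID) {
    rc <- reclassify_euis(fx$model, fx$euis, e0, ecp = ecp)
    expect_equal(sum(rc$U) + rc$unclassified, rc$n_eui)
    expect_gte(rc$unclassified, prev)
    prev <- rc$unclassified
  }
})

test_that("tightening the threshold shrinks the class matrix entrywise", {
  fx <- fixture_fit()
  rec <- fx$known[1:2000, ]
  ecp <- predict_ecp(fx$model, rec)
  cms <- lapply(DEFAULT_ECP_GRID, function(e0)
    build_class_matrix(fx$model, rec, e0, ecp = ecp))
  for (i in seq_along(cms)[-1]) {
    expect_true(all(cms[[i]]$d <= cms[[i - 1]]$d))
    expect_gte(cms[[i]]$unclassified, cms[[i - 1]]$unclassified)
  }
})

test_that("proportional redistribution splits strata by known counts", {
  strata <- data.frame(sex = "male", age_group = c("15-24", "25-34"),
                       NTA = c(60, 0), SUI = c(30, 0), HOM = c(10, 0),
                       eui = c(10, 8), stringsAsFactors = FALSE)
  out <- proportional_redistribution(strata)
  expect_equal(unlist(out[1, c("NTA_redist", "SUI_redist", "HOM_redist")],
                      use.names = FALSE), c(6, 3, 1))
  # empty stratum falls back to the sex margin (60,30,10)/100
  expect_equal(unlist(out[2, c("NTA_redist", "SUI_redist", "HOM_redist")],
                      use.names = FALSE), 8 * c(0.6, 0.3, 0.1))
  expect_equal(rowSums(out[paste0(CAUSE_LEVELS, "_redist")]), strata$eui,
               ignore_attr = TRUE)
  strata0 <- strata; strata0[CAUSE_LEVELS] <- 0
  expect_error(proportional_redistribution(strata0), "margin")
})

test_that("fuzzy sharing credits causes with summed memberships", {
  expect_equal(unname(fuzzy_sharing_redistribution(c(0.8, 0.1, 0.1))),
               c(0.8, 0.1, 0.1))
  n <- 40
  all_nta <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  expect_equal(unname(fuzzy_sharing_redistribution(all_nta)), c(n, 0, 0))
  set.seed(12)
  P <- matrix(rgamma(3 * 25, 1), 25, 3); P <- P / rowSums(P)
  expect_equal(sum(fuzzy_sharing_redistribution(P)), 25)
})

test_that("multinomial pmf matches dmultinom and sums to one", {
  expect_equal(multinomial_pmf(c(10, 0, 0), c(1, 0, 0)), 1)
  set.seed(3)
  for (r in 1:25) {
    p <- rgamma(3, 1); p <- p / sum(p)
    x <- as.vector(stats::rmultinom(1, 12, p))
    expect_equal(multinomial_pmf(x, p),
                 stats::dmultinom(x, prob = p), tolerance = 1e-12)
  }
  # exhaustive: compositions of n = 5 over 3 causes sum to 1
  comps <- expand.grid(a = 0:5, b = 0:5, c = 0:5)
  comps <- comps[rowSums(comps) == 5, ]
  total <- sum(apply(comps, 1, multinomial_pmf, prob = c(0.5, 0.3, 0.2)))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(multinomial_pmf(c(1, 2), c(0.5, 0.3, 0.2)), "length")
  expect_error(multinomial_pmf(c(1, 2, 3), c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(multinomial_pmf(c(1.5, 2, 3), c(0.5, 0.3, 0.2)), "integers")
})

test_that("model-based redistribution diverges from the demographic default
          when homicides hide", {
  cfg <- default_russia_like_config(
    n_records = 40000, masking = masking_hidden_homicide(),
    schema = small_schema(), seed = 55)
  g <- generate_microdata(cfg)
  known <- g$records[g$records$cause_class %in% CAUSE_LEVELS &
                       g$records$sex == "male", ]
  euis <- g$records[g$records$cause_class == "EUI" &
                      g$records$sex == "male", ]
  m <- suppressWarnings(fit_mlogit(known))
  cm <- build_class_matrix(m, known, 0)
  U_adj <- population_adjust(build_misclass_matrix(cm),
                             reclassify_euis(m, euis, 0)$U)
  # demographic default: proportional to known-cause counts
  known_counts <- table(factor(as.character(known$cause_class),
                               levels = CAUSE_LEVELS))
  prop_hom <- known_counts[["HOM"]] / sum(known_counts)
  model_hom <- U_adj[["HOM"]] / sum(U_adj)
  expect_gt(model_hom, prop_hom + 0.1)
  # and the model share tracks the truth better than the default
  true_hom <- mean(g$truth$true_cause[g$records$cause_class == "EUI" &
                                        g$records$sex == "male"] == "HOM")
  expect_lt(abs(model_hom - true_hom), abs(prop_hom - true_hom))
})
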