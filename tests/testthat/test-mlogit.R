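test_that("class weights equalize weighted class totals", {
  expect_equal(unname(compute_class_weights(c(NTA = 100, SUI = 100,
                                              HOM = 100))),
               c(1, 1, 1))
  w <- compute_class_weights(c(NTA = 300, SUI = 150, HOM = 150))
  expect_equal(unname(w), c(600 / 900, 600 / 450, 600 / 450))
  expect_equal(unname(w * c(300, 150, 150)), rep(200, 3))

  set.seed(1)
  for (i in 1:5) {
    n <- sample(50:500, 3)
    names(n) <- CAUSE_LEVELS
    w <- compute_class_weights(n)
    expect_equal(sum(w * n), sum(n))              # weighted n = raw n
    expect_equal(diff(range(w * n)), 0)           # balanced totals
  }
  expect_error(compute_class_weights(c(NTA = 10, SUI = 0, HOM = 5)),
               "present")
})

test_that("intercept-only fits reproduce the closed-form MLE", {
  counts <- c(120, 45, 35)
  y <- rep(1:3, counts)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  # unweighted: fitted probabilities are the empirical shares
  fit <- euireclass:::mlogit_newton(X, y, rep(1, length(y)), 3L, 3L)
  p <- exp(c(fit$B, 0)); p <- p / sum(p)
  expect_equal(p, counts / sum(counts), tolerance = 1e-8)
  # class-balancing weights: fitted probabilities are uniform
  w <- compute_class_weights(setNames(counts, CAUSE_LEVELS))
  fit_w <- euireclass:::mlogit_newton(X, y, unname(w[y]), 3L, 3L)
  p_w <- exp(c(fit_w$B, 0)); p_w <- p_w / sum(p_w)
  expect_equal(p_w, rep(1 / 3, 3), tolerance = 1e-8)
})

test_that("predict_ecp matches direct formula evaluation to 1e-12", {
  fx <- fixture_fit()
  m <- fx$model
  K <- ncol(m$coefficients)
  set.seed(99)
  for (r in 1:100) {
    B <- m$coefficients
    B[m$classes != m$base, ] <- matrix(rnorm(2 * K, sd = 0.8), 2, K)
    x <- rbinom(K, 1, 0.3); x[1] <- 1
    p <- predict_ecp(m, matrix(x, 1), coefficients = B)
    # independent scalar oracle: the softmax formula term by term
    s <- numeric(3)
    for (i in 1:3) for (k in 1:K) s[i] <- s[i] + B[i, k] * x[k]
    oracle <- exp(s) / sum(exp(s))
    expect_equal(unname(drop(p)), oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("predict_ecp is stable, normalized and shift-invariant", {
  fx <- fixture_fit()
  m <- fx$model
  p <- predict_ecp(m, fx$known[1:500, ])
  expect_prob_rows(p)
  expect_true(all(apply(p, 1, max) >= 1 / 3 - 1e-9))
  # zero coefficients -> uniform
  B0 <- m$coefficients * 0
  p0 <- predict_ecp(m, fx$known[1:5, ], coefficients = B0)
  expect_equal(unname(p0), matrix(1 / 3, 5, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # adding a constant to every outcome's score leaves probabilities fixed
  Bc <- m$coefficients; Bc[, 1] <- Bc[, 1] + 50
  expect_equal(unname(predict_ecp(m, fx$known[1:50, ], coefficients = Bc)),
               unname(predict_ecp(m, fx$known[1:50, ])), tolerance = 1e-9,
               ignore_attr = TRUE)
  # huge scores do not overflow
  Bh <- m$coefficients; Bh[1, 1] <- 800
  ph <- predict_ecp(m, fx$known[1:5, ], coefficients = Bh)
  expect_true(all(is.finite(ph)))
  expect_error(predict_ecp(m, matrix(1, 1, 3)), "does not match")
})

test_that("coefficients are recovered from data simulated at known B", {
  ok <- 0; tot <- 0
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 20000
    X <- cbind(`(Intercept)` = 1,
               x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.3),
               x3 = rbinom(n, 1, 0.7))
    Btrue <- rbind(c(0.4, -0.8, 0.5, 0.3), c(-0.2, 0.6, -0.7, 0.4))
    S <- cbind(X %*% t(Btrue), 0)
    P <- exp(S) / rowSums(exp(S))
    y <- vapply(seq_len(n),
                function(i) sample.int(3L, 1L, prob = P[i, ]), 0L)
    fit <- euireclass:::mlogit_newton(X, y, rep(1, n), 3L, 3L)
    z <- abs(fit$B - Btrue) / fit$SE
    ok <- ok + sum(z <= 3); tot <- tot + length(z)
  }
  expect_gte(ok / tot, 0.99)
})

test_that("fitting is invariant to record order and base relabeling", {
  g <- generate_microdata(small_config(n = 5000, seed = 31))
  known <- g$records[g$records$cause_class %in% CAUSE_LEVELS &
                       g$records$sex == "male", ]
  enc <- build_encoding(known, small_schema())
  m1 <- suppressWarnings(fit_mlogit(known, enc))
  set.seed(1)
  shuffled <- known[sample.int(nrow(known)), ]
  m2 <- suppressWarnings(fit_mlogit(shuffled, enc))
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)

  m3 <- suppressWarnings(fit_mlogit(known, enc, base = "NTA"))
  expect_equal(predict_ecp(m1, known[1:200, ]),
               predict_ecp(m3, known[1:200, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  g <- generate_microdata(small_config(n = 3000, seed = 32))
  known <- g$records[g$records$cause_class %in% CAUSE_LEVELS &
                       g$records$sex == "male", ]
  known$season <- ifelse(known$alcohol == "yes", "winter", "summer")
  known <- validate_records(known, small_schema())
  expect_error(suppressWarnings(fit_mlogit(known)), "collinear")
})

test_that("mixed-sex fits are refused unless pooled", {
  g <- generate_microdata(small_config(n = 2000, seed = 33))
  known <- g$records[g$records$cause_class %in% CAUSE_LEVELS, ]
  expect_error(fit_mlogit(known), "both sexes")
  expect_s3_class(suppressWarnings(fit_mlogit(known, pooled = TRUE)),
                  "eui_mlogit")
})

test_that("transport discriminator separates and matches the glm oracle", {
  g <- generate_microdata(small_config(n = 4000, seed = 34,
                                       masking = masking_uniform(0)))
  rec <- g$records[g$records$sex == "male", ]
  # transports get an injury category nothing else uses -> separable
  n_tra <- 400
  is_tra <- seq_len(nrow(rec)) <= n_tra
  rec$injury_category <- as.character(rec$injury_category)
  rec$injury_category[is_tra] <- "11"
  rec$injury_category[!is_tra][rec$injury_category[!is_tra] == "11"] <- "19"
  rec <- validate_records(rec, small_schema())
  expect_warning(md <- fit_transport_discriminator(rec, is_tra),
                 "separation")
  pred <- predict_transport(md, rec)
  expect_lt(mean((pred > 0.5) != is_tra), 0.01)

  # noise-only data: discriminator finds nothing, and the unweighted fit
  # agrees with stats::glm (binomial logit) to 1e-6
  set.seed(8)
  is_noise <- sample(c(TRUE, FALSE), nrow(rec), replace = TRUE)
  rec2 <- g$records[g$records$sex == "male", ]
  mb <- fit_transport_discriminator(rec2, is_noise, weights = "none")
  p2 <- predict_transport(mb, rec2)
  expect_lt(abs(mean(p2) - 0.5), 0.05)
  X <- encode_covariates(rec2, mb$encoding)
  gl <- suppressWarnings(
    stats::glm.fit(X, as.numeric(is_noise), family = stats::binomial()))
  expect_equal(unname(p2), unname(gl$fitted.values), tolerance = 1e-6)
})

test_that("model serialization round-trips at full precision", {
  fx <- fixture_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fx$model, path)
  back <- read_model(path)
  expect_identical(back$coefficients, fx$model$coefficients)
  expect_identical(back$se, fx$model$se)
  expect_identical(back$class_weights, fx$model$class_weights)
  expect_identical(back$base, fx$model$base)
  expect_equal(unname(predict_ecp(back, fx$known[1:100, ])),
               unname(predict_ecp(fx$model, fx$known[1:100, ])),
               ignore_attr = TRUE)
})
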