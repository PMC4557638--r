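#' Class-balancing weights
#'
#' The numbers of deaths differ substantially across the three causes, and
#' an unweighted fit would favour the largest class. The fitting weight for
#' cause c is `N_total / (3 * N_c)`, so every cause has the same weighted
#' total and the weighted sample size equals the raw sample size (keeping
#' standard errors on a comparable scale).
#'
#' @param x Either a vector of observed cause labels or a named count
#'   vector/table over the known causes.
#' @param classes Cause labels in index order.
#' @return Named numeric weights, one per cause.
#' @examples
#' compute_class_weights(c(NTA = 300, SUI = 150, HOM = 150))
#' @export
compute_class_weights <- function(x, classes = CAUSE_LEVELS) {
  counts <- if (is.table(x) || (is.numeric(x) && !is.null(names(x)))) {
    as.numeric(x[classes])
  } else {
    as.numeric(table(factor(as.character(x), levels = classes)))
  }
  if (anyNA(counts) || any(counts == 0)) {
    stop("every cause class must be present to compute class weights")
  }
  n <- sum(counts)
  stats::setNames(n / (length(classes) * counts), classes)
}

# Newton fitting of a case-weighted multinomial logit.
# X: n x K design; y_idx: outcome index 1..m; w: case weights;
# base: base-outcome index (coefficients fixed at zero).
mlogit_newton <- function(X, y_idx, w, m, base,
                          grad_tol = 1e-6, ll_tol = 1e-10, max_iter = 100L) {
  n <- nrow(X); K <- ncol(X)
  free <- setdiff(seq_len(m), base)
  nf <- length(free)

  qrX <- qr(X)
  if (qrX$rank < K) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):K]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  probs <- function(B) {             # B: nf x K, returns n x m
    S <- matrix(0, n, m)
    S[, free] <- X %*% t(B)
    S <- S - apply(S, 1L, max)       # stability shift
    E <- exp(S)
    E / rowSums(E)
  }
  loglik <- function(P) sum(w * log(pmax(P[cbind(seq_len(n), y_idx)],
                                         1e-300)))

  B <- matrix(0, nf, K, dimnames = list(NULL, colnames(X)))
  P <- probs(B)
  ll <- loglik(P)
  Y <- matrix(0, n, m); Y[cbind(seq_len(n), y_idx)] <- 1

  iter <- 0L; gmax <- Inf; converged <- FALSE
  repeat {
    iter <- iter + 1L
    G <- vapply(free, function(a) crossprod(X, w * (Y[, a] - P[, a]))[, 1L],
                numeric(K))                       # K x nf
    gmax <- max(abs(G))
    H <- matrix(0, nf * K, nf * K)
    for (a in seq_len(nf)) {
      for (b in a:nf) {
        wa <- w * P[, free[a]] * ((a == b) - P[, free[b]])
        blk <- crossprod(X, X * wa)
        ra <- (a - 1L) * K + seq_len(K); rb <- (b - 1L) * K + seq_len(K)
        H[ra, rb] <- blk
        if (a != b) H[rb, ra] <- t(blk)
      }
    }
    if (gmax < grad_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, as.vector(G)),
                     error = function(e) stop("Newton step failed (singular ",
                                              "information matrix): ",
                                              conditionMessage(e)))
    step <- matrix(step, nf, K, byrow = TRUE)
    # step-halving: accept only ascent of the weighted log-likelihood
    lambda <- 1; accepted <- FALSE
    for (h in 1:30) {
      B_new <- B + lambda * step
      P_new <- probs(B_new)
      ll_new <- loglik(P_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        accepted <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!accepted) break
    rel_change <- abs(ll_new - ll) / max(1, abs(ll))
    B <- B_new; P <- P_new; ll <- ll_new
    if (rel_change < ll_tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(paste0("multinomial logit did not converge after %d ",
                        "iterations (gradient max-norm %.3g)"), iter, gmax))
  }
  # observed information at the optimum -> standard errors
  H <- matrix(0, nf * K, nf * K)
  for (a in seq_len(nf)) {
    for (b in a:nf) {
      wa <- w * P[, free[a]] * ((a == b) - P[, free[b]])
      blk <- crossprod(X, X * wa)
      ra <- (a - 1L) * K + seq_len(K); rb <- (b - 1L) * K + seq_len(K)
      H[ra, rb] <- blk
      if (a != b) H[rb, ra] <- t(blk)
    }
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nf * K, nf * K))
  SE <- matrix(sqrt(pmax(diag(V), 0)), nf, K, byrow = TRUE,
               dimnames = list(NULL, colnames(X)))
  if (max(abs(B)) > 12) {
    big <- colnames(X)[apply(abs(B) > 12, 2L, any)]
    warning("possible quasi-complete separation; extreme coefficients on: ",
            paste(big, collapse = ", "))
  }
  list(B = B, SE = SE, loglik = ll, iterations = iter, grad_norm = gmax,
       converged = converged)
}

#' Fit the class-weighted multinomial logistic model
#'
#' Maximum-likelihood fit of the three-cause multinomial logit on deaths
#' with known causes, with one outcome (homicide by default) as the base
#' whose coefficients are fixed at zero. Fitting is deterministic (Newton
#' with step-halving, no random initialization) and invariant to record
#' order. Standard errors come from the observed information at the optimum.
#'
#' The pipeline fits men and women separately; pass a single-sex subset
#' (or set `pooled = TRUE` to allow a deliberate pooled fit).
#'
#' @param records Validated records with known causes (`NTA`,`SUI`,`HOM`).
#' @param encoding `eui_encoding`; built from `records` when `NULL`.
#' @param weights Per-class weights; `"balanced"` (default) uses
#'   [compute_class_weights()], `"none"` fits unweighted, or a named
#'   numeric vector over the classes.
#' @param base Base outcome label.
#' @param pooled Set `TRUE` to accept records of both sexes in one fit.
#' @return Object of class `eui_mlogit` with elements `coefficients` and
#'   `se` (3 x K matrices, base row zero), `base`, `classes`,
#'   `class_weights`, `encoding`, `loglik`, `iterations`, `grad_norm`, `n`.
#' @export
fit_mlogit <- function(records, encoding = NULL,
                       weights = "balanced", base = "HOM", pooled = FALSE) {
  records <- records[records$cause_class %in% CAUSE_LEVELS, , drop = FALSE]
  if (!pooled && length(unique(as.character(records$sex))) > 1L) {
    stop("records contain both sexes; fit per sex or set pooled = TRUE")
  }
  y <- factor(as.character(records$cause_class), levels = CAUSE_LEVELS)
  if (length(unique(y)) < 2L) stop("need at least two outcome classes")
  if (is.null(encoding)) encoding <- build_encoding(records)
  X <- encode_covariates(records, encoding)

  cw <- if (identical(weights, "balanced")) {
    compute_class_weights(y)
  } else if (identical(weights, "none")) {
    stats::setNames(rep(1, 3L), CAUSE_LEVELS)
  } else {
    stopifnot(is.numeric(weights), all(CAUSE_LEVELS %in% names(weights)))
    weights[CAUSE_LEVELS]
  }
  base_idx <- match(base, CAUSE_LEVELS)
  if (is.na(base_idx)) stop("unknown base outcome: ", base)

  fit <- mlogit_newton(X, as.integer(y), unname(cw[as.character(y)]),
                       m = 3L, base = base_idx)
  B <- matrix(0, 3L, ncol(X), dimnames = list(CAUSE_LEVELS, colnames(X)))
  SE <- B
  free <- setdiff(1:3, base_idx)
  B[free, ] <- fit$B
  SE[free, ] <- fit$SE
  structure(
    list(coefficients = B, se = SE, base = base, classes = CAUSE_LEVELS,
         class_weights = cw, encoding = encoding,
         loglik = fit$loglik, iterations = fit$iterations,
         grad_norm = fit$grad_norm, converged = fit$converged,
         n = nrow(X)),
    class = "eui_mlogit"
  )
}

#' @export
print.eui_mlogit <- function(x, ...) {
  cat("<eui_mlogit> base =", x$base, "| n =", x$n,
      "| coef:", nrow(x$coefficients), "x", ncol(x$coefficients),
      sprintf("| loglik %.2f after %d iterations\n", x$loglik, x$iterations))
  invisible(x)
}

#' Estimated classification probabilities (ECPs)
#'
#' Evaluates `Pr(cause = i | x) = exp(s_i) / sum_i exp(s_i)` with linear
#' scores `s_i = sum_k B_ik x_k` (base-outcome score zero), computed with a
#' max-score shift for numerical stability.
#'
#' @param model An `eui_mlogit` (or the perturbed-coefficient variant).
#' @param records Data frame of records conforming to the model's encoding,
#'   or an already-encoded design matrix.
#' @param coefficients Optional replacement coefficient matrix (same shape
#'   as `model$coefficients`), e.g. a perturbed matrix from
#'   [perturb_coefficients()].
#' @return Numeric matrix, one row per record, columns `NTA, SUI, HOM`,
#'   rows summing to 1; linear scores attached as attribute `"scores"`.
#' @export
predict_ecp <- function(model, records, coefficients = NULL) {
  stopifnot(inherits(model, "eui_mlogit"))
  B <- if (is.null(coefficients)) model$coefficients else coefficients
  X <- if (is.matrix(records)) records else
    encode_covariates(records, model$encoding)
  if (ncol(X) != ncol(B)) {
    stop("indicator vector length ", ncol(X),
         " does not match model dimension ", ncol(B))
  }
  S <- X %*% t(B)                     # n x 3 linear scores
  Sm <- S - apply(S, 1L, max)
  E <- exp(Sm)
  P <- E / rowSums(E)
  colnames(P) <- model$classes
  attr(P, "scores") <- S
  P
}

#' Binary transport-accident discriminator
#'
#' Sensitivity check: a two-class version of the same weighted fit that
#' separates transport accidents from the combined group of non-transport
#' accidents, suicides and homicides, returning the probability that a
#' record is a transport accident.
#'
#' @param records Validated records (any cause classes).
#' @param is_transport Logical vector flagging transport-accident records.
#' @param encoding `eui_encoding`; built from `records` when `NULL`.
#' @param weights `"balanced"` (default) or `"none"`.
#' @return Object of class `eui_binary` with `coefficients`/`se` (1 x K,
#'   for the transport class against the combined base) and `encoding`;
#'   use [predict_transport()] for probabilities.
#' @export
fit_transport_discriminator <- function(records, is_transport,
                                        encoding = NULL,
                                        weights = "balanced") {
  stopifnot(length(is_transport) == nrow(records))
  if (!any(is_transport) || all(is_transport)) {
    stop("both transport and non-transport records are required")
  }
  if (is.null(encoding)) encoding <- build_encoding(records)
  X <- encode_covariates(records, encoding)
  y_idx <- ifelse(is_transport, 1L, 2L)        # class 2 (other) is base
  w <- if (identical(weights, "balanced")) {
    cnt <- c(sum(is_transport), sum(!is_transport))
    (length(y_idx) / (2 * cnt))[y_idx]
  } else rep(1, length(y_idx))
  fit <- withCallingHandlers(
    mlogit_newton(X, y_idx, w, m = 2L, base = 2L),
    warning = function(w_) invokeRestart("muffleWarning")
  )
  # re-raise separation warning with the binary context
  if (max(abs(fit$B)) > 12) {
    big <- colnames(X)[abs(fit$B[1L, ]) > 12]
    warning("transport discriminator: possible complete separation on: ",
            paste(big, collapse = ", "))
  }
  structure(list(coefficients = fit$B, se = fit$SE, encoding = encoding,
                 loglik = fit$loglik, iterations = fit$iterations),
            class = "eui_binary")
}

#' @rdname fit_transport_discriminator
#' @param model An `eui_binary`.
#' @export
predict_transport <- function(model, records) {
  stopifnot(inherits(model, "eui_binary"))
  X <- if (is.matrix(records)) records else
    encode_covariates(records, model$encoding)
  s <- drop(X %*% t(model$coefficients))
  stats::plogis(s)
}

#' Write / read a fitted model as structured text
#'
#' JSON serialization at full float precision; `read_model` restores a model
#' whose coefficients, standard errors, encoding and weights are identical
#' to the saved ones.
#'
#' @param model An `eui_mlogit`.
#' @param path Output / input file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "eui_mlogit"))
  # doubles as %.17g strings: IEEE-754 round-trip exact, unlike JSON numbers
  num <- function(x) sprintf("%.17g", as.numeric(x))
  payload <- list(
    coefficients = num(t(model$coefficients)), se = num(t(model$se)),
    base = model$base, classes = model$classes,
    class_weights = as.list(stats::setNames(num(model$class_weights),
                                            names(model$class_weights))),
    encoding = lapply(model$encoding$variables, function(v)
      list(levels = v$levels, reference = v$reference)),
    loglik = num(model$loglik), iterations = model$iterations,
    grad_norm = num(model$grad_norm), n = model$n
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vars <- lapply(p$encoding, function(v) {
    list(levels = v$levels, reference = v$reference,
         indicators = setdiff(v$levels, v$reference))
  })
  encoding <- structure(list(variables = vars), class = "eui_encoding")
  k_names <- c("(Intercept)",
               unlist(lapply(names(vars), function(v)
                 paste0(v, ".", vars[[v]]$indicators)), use.names = FALSE))
  B <- matrix(as.numeric(p$coefficients), nrow = 3L, byrow = TRUE,
              dimnames = list(p$classes, k_names))
  SE <- matrix(as.numeric(p$se), nrow = 3L, byrow = TRUE,
               dimnames = list(p$classes, k_names))
  w <- unlist(p$class_weights)[p$classes]
  structure(
    list(coefficients = B, se = SE, base = p$base, classes = p$classes,
         class_weights = stats::setNames(as.numeric(w), names(w)),
         encoding = encoding, loglik = as.numeric(p$loglik),
         iterations = p$iterations, grad_norm = as.numeric(p$grad_norm),
         converged = TRUE, n = p$n),
    class = "eui_mlogit"
  )
}
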