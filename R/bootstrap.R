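#' Perturb fitted coefficients with SE-scaled Gaussian noise
#'
#' One parametric-bootstrap replicate: `B~ = B + SE * gamma` with `gamma`
#' drawn independently per coefficient from the standard normal. The base
#' outcome row stays identically zero. Correlations between coefficient
#' estimates are deliberately ignored (only standard errors enter).
#'
#' @param model Fitted `eui_mlogit` with standard errors.
#' @param seed Optional integer seed for reproducibility.
#' @return Perturbed coefficient matrix, same shape as
#'   `model$coefficients`.
#' @export
perturb_coefficients <- function(model, seed = NULL) {
  stopifnot(inherits(model, "eui_mlogit"))
  SE <- model$se
  if (anyNA(SE)) stop("model has missing standard errors")
  if (!is.null(seed)) set.seed(as.integer(seed))
  B <- model$coefficients
  free <- model$classes != model$base
  noise <- matrix(stats::rnorm(sum(free) * ncol(B)), sum(free), ncol(B))
  B[free, ] <- B[free, ] + SE[free, ] * noise
  B
}

#' Bootstrap stability of predicted causes
#'
#' Generates `n_replicates` perturbed coefficient vectors, repeats the
#' argmax-cause prediction for every record under each, and measures how
#' often the perturbed prediction agrees with the original one. Also
#' reports the minimal ECP level above which every record's prediction was
#' stable across all replicates (the reading behind "above this ECP the
#' predicted cause was always the same").
#'
#' @param model Fitted `eui_mlogit`.
#' @param records Records to score (training set or EUIs).
#' @param n_replicates Number of coefficient perturbations (default 250).
#' @param seed Integer seed; the whole report is reproducible given
#'   (model, records, seed).
#' @return Object of class `eui_bootstrap`: list with `n_replicates`,
#'   `agreement` (per-record fraction of agreeing replicates),
#'   `overall_agreement` (share of record-replicate pairs agreeing),
#'   `stable_ecp_threshold` (minimal original max-ECP above which all
#'   replicates agreed, or `NA` if no such level exists), `max_ecp`
#'   (original per-record maximum ECP), and `seed`.
#' @export
stability_analysis <- function(model, records, n_replicates = 250L,
                               seed = 1L) {
  stopifnot(inherits(model, "eui_mlogit"))
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  X <- encode_covariates(records, model$encoding)
  ecp0_pred <- predict_ecp(model, X)
  orig <- max.col(ecp0_pred, ties.method = "first")
  max_ecp <- ecp0_pred[cbind(seq_along(orig), orig)]

  set.seed(as.integer(seed))
  agree <- integer(length(orig))
  for (r in seq_len(n_replicates)) {
    Br <- perturb_coefficients(model)
    Pr <- predict_ecp(model, X, coefficients = Br)
    agree <- agree + (max.col(Pr, ties.method = "first") == orig)
  }
  frac <- agree / n_replicates
  # smallest observed max-ECP t such that every record with max ECP >= t was
  # stable in all replicates
  ord <- order(max_ecp, decreasing = TRUE)
  stable_run <- cumsum(frac[ord] < 1) == 0
  threshold <- if (all(frac == 1)) 1 / 3
               else if (any(stable_run)) max_ecp[ord][max(which(stable_run))]
               else NA_real_
  structure(
    list(n_replicates = as.integer(n_replicates),
         agreement = frac,
         overall_agreement = mean(frac),
         stable_ecp_threshold = threshold,
         max_ecp = max_ecp,
         seed = as.integer(seed)),
    class = "eui_bootstrap"
  )
}

#' @export
print.eui_bootstrap <- function(x, ...) {
  cat(sprintf(paste0("<eui_bootstrap> %d replicates | overall agreement ",
                     "%.4f | stable above ECP %s\n"),
              x$n_replicates, x$overall_agreement,
              ifelse(is.na(x$stable_ecp_threshold), "none",
                     sprintf("%.3f", x$stable_ecp_threshold))))
  invisible(x)
}
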