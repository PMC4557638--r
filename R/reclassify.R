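#' Default ECP threshold grid
#'
#' The canonical grid: the unconstrained case (0) plus thresholds from 0.5
#' to 0.9.
#' @export
DEFAULT_ECP_GRID <- c(0, 0.5, 0.6, 0.7, 0.75, 0.8, 0.85, 0.9)

#' Assign a cause from estimated classification probabilities
#'
#' The candidate cause is the maximum of the three ECPs; the assignment is
#' accepted only when that maximum is greater than or equal to the threshold
#' `ecp0` (`0` = full flexibility, `1` = absolute constraint). Exact ties on
#' the maximum are broken by the fixed cause-index order (NTA < SUI < HOM)
#' and counted.
#'
#' @param ecp Numeric matrix of ECPs (rows = records, columns in cause
#'   order) or a single length-3 vector.
#' @param ecp0 Threshold in `[0, 1]`.
#' @return Character vector of assigned causes, `NA` for unclassified
#'   records; the number of exact ties is attached as attribute `"ties"`.
#' @examples
#' assign_cause(c(0.8, 0.1, 0.1), 0.75)   # "NTA"
#' assign_cause(c(0.5, 0.3, 0.2), 0.75)   # unclassified
#' @export
assign_cause <- function(ecp, ecp0) {
  if (length(ecp0) != 1L || is.na(ecp0) || ecp0 < 0 || ecp0 > 1) {
    stop("ecp0 must be a single value in [0, 1]")
  }
  if (!is.matrix(ecp)) ecp <- matrix(ecp, nrow = 1L)
  stopifnot(ncol(ecp) == 3L)
  idx <- max.col(ecp, ties.method = "first")
  pmaxv <- ecp[cbind(seq_len(nrow(ecp)), idx)]
  n_ties <- sum(rowSums(ecp == pmaxv) > 1L)
  out <- CAUSE_LEVELS[idx]
  out[pmaxv < ecp0] <- NA_character_
  if (length(out) == 1L) out <- unname(out)
  attr(out, "ties") <- n_ties
  out
}

#' Predicted-by-actual distribution matrix at a threshold
#'
#' Scores labelled records with the model and counts deaths cross-classified
#' by predicted cause i (rows) and actual cause j (columns), keeping only
#' records whose maximum ECP meets the threshold. Records below the
#' threshold are counted as unclassified.
#'
#' @param model Fitted `eui_mlogit`.
#' @param records Validated records with known causes.
#' @param ecp0 ECP threshold.
#' @param ecp Optional precomputed ECP matrix for `records` (saves rescoring
#'   when sweeping a grid).
#' @return Object of class `eui_class_matrix`: list with `d` (3 x 3 counts),
#'   `ecp0`, `unclassified`, `n_scored`, and marginals `D_P` (predicted,
#'   row sums) and `D_A` (actual, column sums).
#' @export
build_class_matrix <- function(model, records, ecp0, ecp = NULL) {
  if (is.null(ecp)) ecp <- predict_ecp(model, records)
  actual <- factor(as.character(records$cause_class), levels = CAUSE_LEVELS)
  if (anyNA(actual)) stop("build_class_matrix needs records with known causes")
  pred <- assign_cause(ecp, ecp0)
  keep <- !is.na(pred)
  d <- table(predicted = factor(pred[keep], levels = CAUSE_LEVELS),
             actual = actual[keep])
  d <- unclass(as.matrix(d))
  structure(
    list(d = d, ecp0 = ecp0, unclassified = sum(!keep),
         n_scored = length(pred),
         D_P = rowSums(d), D_A = colSums(d),
         ties = attr(pred, "ties")),
    class = "eui_class_matrix"
  )
}

#' @export
print.eui_class_matrix <- function(x, ...) {
  cat(sprintf("<eui_class_matrix> ECP0 = %.2f | classified %d / %d\n",
              x$ecp0, sum(x$d), x$n_scored))
  print(x$d)
  invisible(x)
}

#' Relative error of predicted cause totals
#'
#' `(D_i^P - D_i^A) / D_i^A` per cause: how far the predicted marginal
#' totals are from the actual ones. The smaller these errors, the closer
#' the model fits the population-level mortality distribution by cause.
#'
#' @param cm An `eui_class_matrix`.
#' @return Named numeric vector of signed proportions; causes with zero
#'   actual marginal are returned as `NA` with a warning.
#' @export
relative_error <- function(cm) {
  stopifnot(inherits(cm, "eui_class_matrix"))
  out <- (cm$D_P - cm$D_A) / cm$D_A
  if (any(cm$D_A == 0)) {
    warning("relative error undefined for causes with zero actual count")
    out[cm$D_A == 0] <- NA_real_
  }
  out
}

#' Share of agreement between predicted and actual causes
#'
#' @param cm An `eui_class_matrix`.
#' @return List with `overall` (trace over classified total) and
#'   `by_actual` (diagonal over actual marginal, per cause).
#' @export
agreement_share <- function(cm) {
  stopifnot(inherits(cm, "eui_class_matrix"))
  total <- sum(cm$d)
  if (total == 0) stop("no classified records at this threshold")
  list(overall = sum(diag(cm$d)) / total,
       by_actual = ifelse(cm$D_A > 0, diag(cm$d) / cm$D_A, NA_real_))
}

#' Misclassification matrix P
#'
#' Row-normalizes the distribution matrix: `P_ij = d_ij / D_i^P` is the
#' estimated probability that a death classified by the model as cause i
#' was actually caused by cause j. Rows with a zero predicted marginal are
#' flagged as undefined, never silently zeroed.
#'
#' @param cm An `eui_class_matrix`.
#' @return Object of class `eui_misclass_matrix`: list with `P` (3 x 3,
#'   defined rows summing to 1) and `undefined_rows` (logical per cause).
#' @export
build_misclass_matrix <- function(cm) {
  stopifnot(inherits(cm, "eui_class_matrix"))
  undef <- cm$D_P == 0
  P <- cm$d / ifelse(cm$D_P == 0, NA_real_, cm$D_P)
  structure(list(P = P, undefined_rows = undef, ecp0 = cm$ecp0),
            class = "eui_misclass_matrix")
}

#' @export
print.eui_misclass_matrix <- function(x, ...) {
  cat("<eui_misclass_matrix>\n")
  print(round(x$P, 4))
  if (any(x$undefined_rows)) {
    cat("undefined rows:",
        paste(CAUSE_LEVELS[x$undefined_rows], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reclassify events of undetermined intent at a threshold
#'
#' Applies the coefficients fitted on known-cause deaths to the EUI records
#' and counts the deaths assigned to each cause (`U_i`), plus those left
#' unclassified because their maximum ECP falls below the threshold.
#'
#' @param model Fitted `eui_mlogit`.
#' @param eui_records Records whose observed `cause_class` is `EUI`.
#' @param ecp0 ECP threshold.
#' @param ecp Optional precomputed ECP matrix.
#' @return List with `U` (named counts per cause), `unclassified`,
#'   `n_eui`, `ecp0`.
#' @export
reclassify_euis <- function(model, eui_records, ecp0, ecp = NULL) {
  if (is.null(ecp)) ecp <- predict_ecp(model, eui_records)
  pred <- assign_cause(ecp, ecp0)
  U <- table(factor(pred, levels = CAUSE_LEVELS))
  list(U = stats::setNames(as.numeric(U), CAUSE_LEVELS),
       unclassified = sum(is.na(pred)), n_eui = length(pred), ecp0 = ecp0)
}

#' Population-level adjustment of EUI cause counts
#'
#' Under the assumption that EUIs share the misclassification behaviour of
#' deaths with known causes, the transposed misclassification matrix
#' redistributes the model-assigned EUI counts at the population level:
#' `U_j^Adj = sum_i P_ij * U_i`. The adjustment conserves the total
#' (`sum_j U_j^Adj = sum_i U_i`), mirroring the training-set identity
#' `D_j^A = sum_i P_ij * D_i^P`.
#'
#' @param mm An `eui_misclass_matrix`.
#' @param U Named counts of EUIs assigned per predicted cause.
#' @return Named numeric vector `U_adj` of population-adjusted counts.
#' @export
population_adjust <- function(mm, U) {
  stopifnot(inherits(mm, "eui_misclass_matrix"), length(U) == 3L)
  U <- if (is.null(names(U))) stats::setNames(as.numeric(U), CAUSE_LEVELS)
       else U[CAUSE_LEVELS]
  if (any(mm$undefined_rows & U > 0)) {
    stop("misclassification row undefined for a cause with nonzero EUI count")
  }
  P <- mm$P
  P[mm$undefined_rows, ] <- 0
  stats::setNames(as.numeric(crossprod(P, U)), CAUSE_LEVELS)
}

#' Comparator: sex/age-proportional redistribution
#'
#' The default demographic solution: within each sex-by-age stratum, EUIs
#' are shared among the three causes proportionally to the stratum's
#' known-cause counts. Strata with no known-cause deaths fall back to the
#' sex-level margin.
#'
#' @param strata Data frame with columns `sex`, `age_group`, `NTA`, `SUI`,
#'   `HOM` (known-cause counts) and `eui` (EUI count) per stratum.
#' @return `strata` with added columns `NTA_redist`, `SUI_redist`,
#'   `HOM_redist`; totals per stratum are conserved.
#' @export
proportional_redistribution <- function(strata) {
  need <- c("sex", "age_group", CAUSE_LEVELS, "eui")
  stopifnot(all(need %in% names(strata)))
  known <- as.matrix(strata[, CAUSE_LEVELS])
  tot <- rowSums(known)
  sex_margin <- rowsum(known, group = as.character(strata$sex))
  if (any(rowSums(sex_margin) == 0)) {
    stop("a sex margin has no known-cause deaths; cannot redistribute")
  }
  shares <- known / tot
  for (r in which(tot == 0)) {
    m <- sex_margin[as.character(strata$sex[r]), ]
    shares[r, ] <- m / sum(m)
  }
  redist <- shares * strata$eui
  colnames(redist) <- paste0(CAUSE_LEVELS, "_redist")
  cbind(strata, as.data.frame(redist))
}

#' Comparator: fuzzy proportional-sharing redistribution
#'
#' Treats each EUI's ECP vector as membership in three fuzzy sets of deaths
#' and credits each cause with the sum of its membership over all EUIs:
#' `total_i = sum_n p_i(n)`. Totals sum to the number of EUIs.
#'
#' @param ecp ECP matrix for the EUI records (rows = records).
#' @return Named numeric cause totals.
#' @export
fuzzy_sharing_redistribution <- function(ecp) {
  if (!is.matrix(ecp)) ecp <- matrix(ecp, nrow = 1L)
  stopifnot(ncol(ecp) == 3L)
  stats::setNames(colSums(ecp), CAUSE_LEVELS)
}

#' Multinomial probability mass
#'
#' Probability of observing a given composition of causes in independent
#' draws: `n! / prod(c_i!) * prod(p_i^c_i)`, computed in log space.
#' For example, the probability of 8 accidents, 1 suicide and 1 homicide in
#' ten trials with class probabilities (0.8, 0.1, 0.1) is 0.151.
#'
#' @param counts Nonnegative integer counts per cause.
#' @param prob Class probabilities, summing to 1.
#' @return The probability mass.
#' @examples
#' multinomial_pmf(c(8, 1, 1), c(0.8, 0.1, 0.1))
#' @export
multinomial_pmf <- function(counts, prob) {
  if (length(counts) != length(prob)) {
    stop("counts and prob must have the same length")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-9) {
    stop("prob must be nonnegative and sum to 1")
  }
  n <- sum(counts)
  lterm <- ifelse(counts == 0, 0, counts * log(prob))  # 0*log(0) := 0
  if (any(prob == 0 & counts > 0)) return(0)
  exp(lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(lterm))
}
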