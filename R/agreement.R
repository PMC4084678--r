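# Confusion-matrix statistics and Cohen's kappa agreement diagnostics.
#
# The convention throughout is: rows = assigned (rater/system) label,
# columns = true (or second-rater) label.

#' Build a confusion matrix from label vectors
#'
#' @param assigned,truth label vectors of equal length.
#' @param labels class ordering; defaults to the sorted union.
#' @return square integer matrix with `labels` as both dimnames; rows are
#'   the assigned label, columns the true label.
#' @export
confusion_matrix <- function(assigned, truth,
                             labels = sort(union(assigned, truth))) {
  assigned <- factor(as.character(assigned), levels = labels)
  truth <- factor(as.character(truth), levels = labels)
  if (anyNA(assigned) || anyNA(truth))
    stopf("labels outside the supplied `labels` set")
  m <- table(assigned = assigned, truth = truth)
  unclass(as.matrix(m))
}

check_square_counts <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("expected a square confusion matrix")
  if (any(m < 0) || anyNA(m)) stopf("counts must be nonnegative")
  if (sum(m) == 0) stopf("confusion matrix is empty")
  invisible(m)
}

#' Per-class recall and binary sensitivity/specificity
#'
#' Recall of class c is the fraction of truly-c samples assigned c (its
#' column-normalised diagonal entry). When a positive class -- or a
#' positive superclass such as `c("HCC", "LM")` for "malignant" -- is
#' designated, the matrix is collapsed to 2x2 and sensitivity (recall of
#' positive) and specificity (recall of negative) are reported.
#'
#' @param m square count matrix, rows = assigned, cols = true.
#' @param positive `NULL`, or character vector of the class(es) forming the
#'   positive superclass.
#' @return list with `recall` (named vector, `NA` for classes absent from
#'   the truth), `accuracy`, and -- when `positive` is given --
#'   `sensitivity` and `specificity`.
#' @examples
#' m <- rbind(c(45, 5), c(5, 45))
#' dimnames(m) <- list(c("a", "b"), c("a", "b"))
#' class_metrics(m, positive = "a")
#' @export
class_metrics <- function(m, positive = NULL) {
  check_square_counts(m)
  cols <- colSums(m)
  recall <- ifelse(cols > 0, diag(m) / cols, NA_real_)
  names(recall) <- colnames(m)
  out <- list(recall = recall, accuracy = sum(diag(m)) / sum(m))
  if (!is.null(positive)) {
    labs <- colnames(m) %||% as.character(seq_len(ncol(m)))
    if (!all(positive %in% labs)) stopf("`positive` not among matrix labels")
    pos <- labs %in% positive
    tp <- sum(m[pos, pos]); fn <- sum(m[!pos, pos])
    tn <- sum(m[!pos, !pos]); fp <- sum(m[pos, !pos])
    out$sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  out
}

#' Cohen's kappa with standard error and confidence interval
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, where `po` is
#' the observed agreement and `pe` the agreement expected from the
#' marginals. The default treats categories as nominal (unweighted);
#' `weighting = "linear"` scores partial agreement between ordered
#' categories with weights `w_ij = 1 - |i - j| / (k - 1)`.
#'
#' The standard error is the large-sample (asymptotic) form of Fleiss,
#' Cohen and Everitt. Writing `p_ij` for cell proportions and
#' `wbar_i. = sum_j p_.j w_ij`, `wbar_.j = sum_i p_i. w_ij` for the
#' marginal-weighted row/column scores, the variance is
#' `var = [ sum_ij p_ij (w_ij (1 - pe) - (wbar_i. + wbar_.j)(1 - po))^2
#'          - (po pe - 2 pe + po)^2 ] / (n (1 - pe)^4)`,
#' which with identity weights reduces to the familiar unweighted formula.
#'
#' @param m square count matrix (rows rater A / assigned, cols rater B /
#'   true).
#' @param weighting `"unweighted"` (default) or `"linear"`.
#' @param conf_level confidence level for the Wald interval, default 0.95.
#' @return object of class `"kappa_result"`: `kappa`, `standard_error`,
#'   `ci95` (clipped to \[-1, 1\]), `strength` (see [strength_band()]),
#'   `weighting`, `po`, `pe`, `n`.
#' @examples
#' m <- rbind(c(45, 5), c(5, 45))
#' cohen_kappa(m)   # kappa 0.8: po = 0.9, pe = 0.5
#' @export
cohen_kappa <- function(m, weighting = c("unweighted", "linear"),
                        conf_level = 0.95) {
  weighting <- match.arg(weighting)
  check_square_counts(m)
  k <- ncol(m)
  n <- sum(m)
  p <- m / n
  pr <- rowSums(p); pc <- colSums(p)
  w <- if (weighting == "unweighted" || k == 1) diag(k)
       else 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < 1e-12)
    stopf("degenerate marginals: expected agreement is 1, kappa undefined")
  kap <- (po - pe) / (1 - pe)

  # asymptotic variance (Fleiss, Cohen & Everitt large-sample form)
  wr <- as.vector(w %*% pc)   # w_i. : column-marginal-weighted row scores
  wc <- as.vector(pr %*% w)   # w_.j : row-marginal-weighted column scores
  term <- outer(wr, wc, "+")
  var_k <- (sum(p * (w * (1 - pe) - term * (1 - po))^2) -
              (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  # the conventional 1.96 multiplier at the default level, as reported in
  # the diagnostic-agreement literature; exact quantile otherwise
  zq <- if (conf_level == 0.95) 1.96 else stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, kap - zq * se), min(1, kap + zq * se))

  structure(list(kappa = kap, standard_error = se, ci95 = ci,
                 strength = strength_band(kap), weighting = weighting,
                 po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa (%s) = %.3f  SE %.3f  95%% CI %.3f-%.3f  [%s]\n",
    x$weighting, x$kappa, x$standard_error, x$ci95[1], x$ci95[2],
    x$strength))
  invisible(x)
}

#' Strength-of-agreement band for a kappa value
#'
#' Maps kappa to the conventional qualitative bands: negligible
#' (0.00-0.20), slight (0.21-0.40), moderate (0.41-0.60), great
#' (0.61-0.80) and excellent (0.81-1.00). The printed bands leave gaps at
#' the boundaries (0.20 vs 0.21); the implementation closes them with
#' half-open intervals split at the rounding midpoints 0.205, 0.405,
#' 0.605, 0.805, which reproduces every banded example. Negative kappa
#' (worse-than-chance agreement) maps to "negligible".
#'
#' @param kappa numeric in \[-1, 1\] (vectorized).
#' @return character vector of band names.
#' @export
strength_band <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1 - 1e-9) || any(kappa > 1 + 1e-9))
    stopf("kappa must be in [-1, 1]")
  bands <- c("negligible", "slight", "moderate", "great", "excellent")
  cuts <- c(-Inf, 0.205, 0.405, 0.605, 0.805, Inf)
  bands[findInterval(kappa, cuts, left.open = FALSE)]
}

#' Write a kappa report row to CSV
#'
#' @param results a `"kappa_result"` or list of them; names become the
#'   `comparison` column.
#' @param path file to write.
#' @return the data frame written, invisibly.
#' @export
write_kappa_csv <- function(results, path) {
  if (inherits(results, "kappa_result")) results <- list(result = results)
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, kappa = r$kappa, se = r$standard_error,
               ci_low = r$ci95[1], ci_high = r$ci95[2],
               strength = r$strength, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
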