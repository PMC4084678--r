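# Two-stage classifier cascade.
#
# Stage 1 labels every image malignant or benign from its 8 FD summary
# features. Stage 2 sees only cases with at least one malignant-flagged
# image: it receives the per-case mean of the malignant images' median FDs
# (nuclei, vessels) and decides hepatocellular carcinoma (HCC) versus
# liver metastasis (LM). A case with no malignant-flagged image is
# reported benign and stage 2 never runs.

#' Fit the two-stage diagnosis cascade
#'
#' Trains the stage-1 image classifier on all images and the stage-2 case
#' classifier on per-case features aggregated over the truly tumour-labeled
#' images (ground-truth flags are used for stage-2 training; at prediction
#' time the stage-1 flags gate the aggregation).
#'
#' @param x numeric matrix of per-image features, one row per image, in
#'   [feature_vector()] column order.
#' @param image_label per-image truth, `"tumor"` or `"normal"`.
#' @param case_id per-image case identifier.
#' @param case_label per-image case truth, `"HCC"` or `"LM"` (constant
#'   within a case).
#' @param hidden hidden-layer width for both stages; default 10.
#' @param seed root seed; the two stage fits use derived substreams.
#' @param ... further arguments passed to both [fdnn()] fits.
#' @return object of class `"fd_cascade"` with elements `stage1`,
#'   `stage2` (both `"fdnn"`) and `feature_names`.
#' @export
fd_cascade <- function(x, image_label, case_id, case_label, hidden = 10,
                       seed = 1, ...) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(image_label), nrow(x) == length(case_id),
            nrow(x) == length(case_label))
  if (!all(image_label %in% c("tumor", "normal")))
    stopf("`image_label` must be 'tumor' or 'normal'")
  y1 <- ifelse(image_label == "tumor", "malignant", "benign")
  stage1 <- fdnn(x, y1, hidden = hidden, seed = derive_seed(seed, "stage1"),
                 ...)

  # per-case stage-2 features from the truly malignant images
  cases <- unique(case_id)
  feats <- t(vapply(cases, function(cs) {
    sel <- case_id == cs & image_label == "tumor"
    c(nuclei_mean_median = mean(x[sel, 1]),
      vessel_mean_median = mean(x[sel, 5]))
  }, numeric(2)))
  y2 <- case_label[match(cases, case_id)]
  keep <- !is.na(feats[, 1])
  stage2 <- fdnn(feats[keep, , drop = FALSE], y2[keep], hidden = hidden,
                 seed = derive_seed(seed, "stage2"), ...)

  structure(list(stage1 = stage1, stage2 = stage2,
                 feature_names = colnames(x)),
            class = "fd_cascade")
}

#' @export
print.fd_cascade <- function(x, ...) {
  cat("two-stage FD cascade\n")
  cat("stage 1 (image: malignant vs benign):\n  ")
  print(x$stage1)
  cat("stage 2 (case: HCC vs LM):\n  ")
  print(x$stage2)
  invisible(x)
}

#' Classify one case through the cascade
#'
#' @param stage1,stage2 fitted `"fdnn"` models (image- and case-level).
#' @param images per-image features for one case: either an `n x 8`
#'   matrix in [feature_vector()] order or a list of `"image_features"`.
#' @return object of class `"cascade_result"`: `image_predictions` (list,
#'   one per image), `malignant_flags`, `case_features` (the stage-2
#'   input: means of the flagged images' median FDs), `case_prediction`
#'   (an `"fdnn_prediction"`, or `NULL` when no image is flagged
#'   malignant) and `final_case_label` (`"HCC"`, `"LM"` or `"benign"`).
#' @export
cascade_classify <- function(stage1, stage2, images) {
  if (is.list(images) && !is.matrix(images))
    images <- feature_vector(images)
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  preds <- predict(stage1, images, type = "prediction")
  flags <- vapply(preds, function(p) p$label == "malignant", TRUE)
  if (!any(flags)) {
    return(structure(list(image_predictions = preds,
                          malignant_flags = flags,
                          case_prediction = NULL,
                          final_case_label = "benign"),
                     class = "cascade_result"))
  }
  cf <- c(nuclei_mean_median = mean(images[flags, 1]),
          vessel_mean_median = mean(images[flags, 5]))
  cp <- predict(stage2, cf, type = "prediction")[[1]]
  structure(list(image_predictions = preds, malignant_flags = flags,
                 case_features = cf,
                 case_prediction = cp, final_case_label = cp$label),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  n <- length(x$malignant_flags)
  cat(sprintf("case: %d/%d images flagged malignant -> %s", sum(x$malignant_flags),
              n, x$final_case_label))
  if (!is.null(x$case_prediction))
    cat(sprintf(" (probability score %.1f%%)", x$case_prediction$probability_score))
  cat("\n")
  invisible(x)
}

#' Predict case labels for a cohort
#'
#' @param object an `"fd_cascade"` fit.
#' @param newdata per-image feature matrix (rows in [feature_vector()]
#'   order).
#' @param case_id per-row case identifier.
#' @param ... unused.
#' @return named list of `"cascade_result"`, one per case (in order of
#'   first appearance).
#' @export
predict.fd_cascade <- function(object, newdata, case_id, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(nrow(newdata) == length(case_id))
  cases <- unique(case_id)
  out <- lapply(cases, function(cs)
    cascade_classify(object$stage1, object$stage2,
                     newdata[case_id == cs, , drop = FALSE]))
  names(out) <- as.character(cases)
  out
}
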