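# Aggregation of per-element fractal dimensions into the fixed-length
# feature vectors consumed by the two classifier stages.
#
# Stage 1 (malignant vs benign, per image) sees 8 numbers: median, min,
# max FD and element count for each of the two channels. Stage 2 (HCC vs
# liver metastasis, per case) sees the two mean malignant-image median FDs.
# A feed-forward network has a fixed input width, so the variable-length
# multiset of element FDs is reduced to these order statistics; they are
# the same summaries by which the FD distributions of the two tumour types
# separate. The element count is kept because metastases show a relative
# paucity of immunolabeled vessels compared with HCC, which the FDs alone
# do not encode.

#' Per-image FD feature summary
#'
#' @param nuclei_fds,vessel_fds numeric vectors of per-element fractal
#'   dimensions for the two channels; either may be empty, not both.
#' @param case_id,image_id identifiers carried through.
#' @return object of class `"image_features"`: a list with `case_id`,
#'   `image_id` and, per channel, `median_fd`, `min_fd`, `max_fd`,
#'   `element_count`. A channel with no elements gets the sentinel
#'   (0, 0, 0, count 0); downstream models treat "no detected elements"
#'   as information (vessel paucity), not as missing data.
#' @export
summarize_image <- function(nuclei_fds, vessel_fds,
                            case_id = NA, image_id = NA) {
  if (length(nuclei_fds) == 0 && length(vessel_fds) == 0)
    stopf("degenerate image: no elements in either channel")
  one <- function(fds) {
    if (length(fds) == 0)
      return(list(median_fd = 0, min_fd = 0, max_fd = 0, element_count = 0L))
    list(median_fd = median(fds), min_fd = min(fds), max_fd = max(fds),
         element_count = length(fds))
  }
  structure(list(case_id = case_id, image_id = image_id,
                 nuclei = one(nuclei_fds), vessels = one(vessel_fds)),
            class = "image_features")
}

#' Flatten image features to the stage-1 input vector
#'
#' @param feats an `"image_features"` object or a list of them.
#' @return a named numeric vector of length 8 (or a matrix, one row per
#'   image) in the fixed order: nuclei median/min/max/count, then vessels
#'   median/min/max/count.
#' @export
feature_vector <- function(feats) {
  if (inherits(feats, "image_features")) feats <- list(feats)
  m <- t(vapply(feats, function(f) {
    c(nuclei_median = f$nuclei$median_fd, nuclei_min = f$nuclei$min_fd,
      nuclei_max = f$nuclei$max_fd, nuclei_count = as.numeric(f$nuclei$element_count),
      vessel_median = f$vessels$median_fd, vessel_min = f$vessels$min_fd,
      vessel_max = f$vessels$max_fd, vessel_count = as.numeric(f$vessels$element_count))
  }, numeric(8)))
  if (nrow(m) == 1) m[1, ] else m
}

#' Per-case features from malignant-flagged images
#'
#' Averages the per-image median FDs over the images flagged malignant,
#' producing the stage-2 input (mean malignant nuclear median FD, mean
#' malignant vascular median FD).
#'
#' @param image_feats list of `"image_features"` for one case.
#' @param malignant_flags logical vector, one per image.
#' @return object of class `"case_features"`: `case_id`,
#'   `mean_malignant_median_fd_nuclei`, `mean_malignant_median_fd_vessels`,
#'   `n_malignant_images` -- or `NULL` when no image is flagged (the case
#'   carries no malignant evidence and stage 2 is skipped).
#' @export
summarize_case <- function(image_feats, malignant_flags) {
  stopifnot(length(image_feats) == length(malignant_flags))
  if (!any(malignant_flags)) return(NULL)
  sel <- image_feats[malignant_flags]
  structure(list(
    case_id = sel[[1]]$case_id,
    mean_malignant_median_fd_nuclei =
      mean(vapply(sel, function(f) f$nuclei$median_fd, 0)),
    mean_malignant_median_fd_vessels =
      mean(vapply(sel, function(f) f$vessels$median_fd, 0)),
    n_malignant_images = sum(malignant_flags)),
    class = "case_features")
}

#' Stage-2 input vector for a case
#'
#' @param cf a `"case_features"` object.
#' @return named numeric vector of length 2 (mean nuclei median FD, mean
#'   vessel median FD over malignant-flagged images).
#' @export
case_feature_vector <- function(cf) {
  stopifnot(inherits(cf, "case_features"))
  c(nuclei_mean_median = cf$mean_malignant_median_fd_nuclei,
    vessel_mean_median = cf$mean_malignant_median_fd_vessels)
}
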