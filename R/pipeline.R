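# Pipeline wiring: configuration, per-image processing, and the batch
# commands (segment, fd, full run) used by the command-line script.

pkg_version <- function() {
  as.character(utils::packageVersion("hepfract"))
}

#' Default pipeline configuration
#'
#' Channel thresholds, element filters and network hyper-parameters in one
#' validated list. Nuclei exclude border-touching components (incomplete
#' nuclei truncate the contour whose complexity is being measured);
#' vessels keep them, since vessels legitimately cross the field of view.
#'
#' @return a named list; see the vignette for every entry and its
#'   rationale.
#' @export
default_config <- function() {
  list(
    channels = list(
      nuclei = list(reference_hue = 240, hue_tolerance = 35,
                    min_saturation = 0.25, exclude_border = TRUE),
      vessels = list(reference_hue = 25, hue_tolerance = 35,
                     min_saturation = 0.25, exclude_border = FALSE)),
    min_pixels = 10,
    connectivity = 8,
    flatten_value = 1.0,
    ann = list(hidden = 10, learning_rate = 0.05, max_epochs = 500,
               patience = 25, batch_size = 32, cv_folds = 10),
    seed = 1)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys
#' are rejected rather than silently ignored, so typos in a config file
#' fail loudly.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "config")
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, where) {
  if (!is.list(user)) stopf("'%s' must be a mapping", where)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stopf("unknown config key%s under '%s': %s",
          if (length(unknown) > 1) "s" else "", where,
          paste(unknown, collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]], paste(where, k, sep = "."))
    else user[[k]]
  }
  base
}

validate_config <- function(cfg) {
  for (ch in names(cfg$channels)) {
    s <- cfg$channels[[ch]]
    channel_spec(s$reference_hue, s$hue_tolerance, s$min_saturation, ch)
  }
  if (cfg$min_pixels < 1) stopf("min_pixels must be >= 1")
  if (!cfg$connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  if (cfg$flatten_value < 0 || cfg$flatten_value > 1)
    stopf("flatten_value must be in [0, 1]")
  invisible(cfg)
}

config_hash <- function(cfg) {
  sprintf("%08x", fnv1a32(paste(deparse(cfg), collapse = "")))
}

# CSV with a provenance comment line; read back with
# read.csv(..., comment.char = "#").
write_csv_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hepfract %s config=%s", pkg_version(),
                     config_hash(cfg)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Segment one image into channel masks and elements
#'
#' Runs the full segmentation chain: HSV conversion, value flattening,
#' per-channel hue/saturation thresholding, connected-component
#' extraction with the size filter and the per-channel border rule.
#'
#' @param rgb numeric RGB array `h x w x 3` in \[0, 1\].
#' @param config a [pipeline_config()] list.
#' @return list with `masks` (logical matrices per channel) and
#'   `elements` (per-channel output of [extract_elements()]).
#' @export
segment_image <- function(rgb, config = default_config()) {
  hsv <- flatten_value(rgb_to_hsv(rgb), config$flatten_value)
  masks <- list(); elements <- list()
  for (ch in names(config$channels)) {
    s <- config$channels[[ch]]
    spec <- channel_spec(s$reference_hue, s$hue_tolerance,
                         s$min_saturation, ch)
    masks[[ch]] <- segment_channel(hsv, spec)
    elements[[ch]] <- extract_elements(masks[[ch]], config$min_pixels,
                                       exclude_border = isTRUE(s$exclude_border),
                                       connectivity = config$connectivity)
  }
  list(masks = masks, elements = elements)
}

# Per-image features (and optional ground-truth agreement) from a rendered
# or loaded image. Returns NULL for a degenerate image with no elements.
process_image <- function(rgb, config, case_id = NA, image_id = NA,
                          truth = NULL) {
  seg <- segment_image(rgb, config)
  fds <- lapply(seg$elements, function(els)
    vapply(els, function(el) element_fd(el)$fd, 0))
  if (length(fds$nuclei) == 0 && length(fds$vessels) == 0) return(NULL)
  feats <- summarize_image(fds$nuclei, fds$vessels,
                           case_id = case_id, image_id = image_id)
  out <- list(features = feats, seg = seg, fds = fds)
  if (!is.null(truth)) {
    out$quality <- lapply(names(seg$masks), function(ch) {
      pred <- seg$masks[[ch]]; tru <- truth[[ch]]
      c(tp = sum(pred & tru), fp = sum(pred & !tru), fn = sum(!pred & tru))
    })
    names(out$quality) <- names(seg$masks)
  }
  out
}

#' Segment a manifest of images on disk
#'
#' @param manifest data frame with columns `path`, `case_id`, `slide_id`,
#'   `image_id` (as written by [generate_cohort()]); or the path of a
#'   manifest CSV.
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory; channel masks are written to
#'   `out_dir/masks/` and the element table to `out_dir/elements.csv`.
#' @return invisibly, a list with the `elements` data frame and `skipped`
#'   (paths that could not be read; these are logged, not fatal).
#' @export
run_segment <- function(manifest, config = default_config(),
                        out_dir = "segmentation") {
  manifest <- as_manifest(manifest)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    rgb <- tryCatch(read_image(r$path), error = function(e) NULL)
    if (is.null(rgb)) {
      message(sprintf("skipping unreadable image: %s", r$path))
      skipped <- c(skipped, r$path)
      next
    }
    seg <- segment_image(rgb, config)
    stem <- tools::file_path_sans_ext(basename(r$path))
    for (ch in names(seg$masks)) {
      write_mask(seg$masks[[ch]],
                 file.path(out_dir, "masks", sprintf("%s_%s.png", stem, ch)))
      els <- seg$elements[[ch]]
      if (length(els) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          case_id = r$case_id, slide_id = r$slide_id, image_id = r$image_id,
          channel = ch,
          element_id = vapply(els, `[[`, 0L, "element_id"),
          pixel_count = vapply(els, `[[`, 0L, "pixel_count"),
          stringsAsFactors = FALSE)
    }
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = integer(0), slide_id = integer(0),
               image_id = integer(0), channel = character(0),
               element_id = integer(0), pixel_count = integer(0))
  write_csv_artifact(elements, file.path(out_dir, "elements.csv"), config)
  message(sprintf("segmented %d images (%d elements, %d skipped)",
                  nrow(manifest) - length(skipped), nrow(elements),
                  length(skipped)))
  invisible(list(elements = elements, skipped = skipped))
}

#' Batch fractal dimensions for a manifest of images
#'
#' Segments each image and writes one row per surviving element with its
#' box-counting FD, in manifest order.
#'
#' @inheritParams run_segment
#' @param out_csv output CSV path.
#' @return invisibly, the FD data frame (`case_id`, `slide_id`,
#'   `image_id`, `channel`, `element_id`, `pixel_count`, `fd`).
#' @export
run_fd <- function(manifest, config = default_config(),
                   out_csv = "fd.csv") {
  manifest <- as_manifest(manifest)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    rgb <- tryCatch(read_image(r$path), error = function(e) NULL)
    if (is.null(rgb)) {
      message(sprintf("skipping unreadable image: %s", r$path))
      next
    }
    seg <- segment_image(rgb, config)
    for (ch in names(seg$elements))
      rows[[length(rows) + 1]] <- element_fd_table(
        seg$elements[[ch]], channel = ch, case_id = r$case_id,
        slide_id = r$slide_id, image_id = r$image_id)
  }
  fd <- do.call(rbind, rows)
  write_csv_artifact(fd, out_csv, config)
  invisible(fd)
}

as_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "case_id", "slide_id", "image_id")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  manifest
}

#' Extract per-image features from a synthetic cohort
#'
#' Streams through the cohort (regenerating each image from its seed
#' substream, so nothing is held in memory), segments it, computes element
#' FDs and the 8 per-image summary features, and accumulates pixel-level
#' segmentation agreement against the ground-truth masks.
#'
#' @param cohort a `"synthetic_cohort"` from [generate_cohort()].
#' @param config a [pipeline_config()] list.
#' @param progress print a note every `progress` images; 0 for silence.
#' @return list with `features` (data frame: manifest columns plus the 8
#'   feature columns) and `seg_quality` (per-channel pixel recall and
#'   precision pooled over all images).
#' @export
cohort_features <- function(cohort, config = default_config(),
                            progress = 0) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  mf <- cohort$manifest
  fmat <- matrix(NA_real_, nrow(mf), 8)
  qual <- list(nuclei = c(tp = 0, fp = 0, fn = 0),
               vessels = c(tp = 0, fp = 0, fn = 0))
  for (i in seq_len(nrow(mf))) {
    r <- mf[i, ]
    im <- cohort$image_fn(r$case_id, r$slide_id, r$image_id)
    pr <- process_image(im$rgb, config, case_id = r$case_id,
                        image_id = r$image_id,
                        truth = list(nuclei = im$nuclei_mask,
                                     vessels = im$vessels_mask))
    if (is.null(pr)) next
    fmat[i, ] <- feature_vector(pr$features)
    for (ch in names(qual)) qual[[ch]] <- qual[[ch]] + pr$quality[[ch]]
    if (progress > 0 && i %% progress == 0)
      message(sprintf("processed %d/%d images", i, nrow(mf)))
  }
  colnames(fmat) <- c("nuclei_median", "nuclei_min", "nuclei_max",
                      "nuclei_count", "vessel_median", "vessel_min",
                      "vessel_max", "vessel_count")
  seg_quality <- lapply(qual, function(q)
    c(recall = unname(q["tp"] / (q["tp"] + q["fn"])),
      precision = unname(q["tp"] / (q["tp"] + q["fp"]))))
  list(features = cbind(mf, as.data.frame(fmat)), seg_quality = seg_quality)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Feature extraction, cascade training, and evaluation in one call:
#' trains the two-stage cascade on the cohort's per-image features, then
#' classifies every case through the cascade and scores the result
#' against the ground truth (image-level and case-level confusion
#' matrices, Cohen's kappa of the system's image labels against truth).
#'
#' Stage-1 accuracy is reported on the held-out test quarter of the
#' 50/25/25 split, which never enters training or early stopping.
#'
#' @param cohort a `"synthetic_cohort"`; all images must carry labels.
#' @param config a [pipeline_config()] list.
#' @param out_dir optional directory for CSV/JSON artifacts (feature
#'   table, confusion matrices, kappa report, serialized models).
#' @param progress see [cohort_features()].
#' @return list with `features`, `seg_quality`, `cascade`,
#'   `stage1_test_accuracy`, `case_results`, `case_confusion`,
#'   `case_accuracy`, `image_confusion` (3-class: system HCC/LM/normal vs
#'   truth) and `image_kappa`.
#' @export
run_full <- function(cohort, config = default_config(), out_dir = NULL,
                     progress = 0) {
  cf <- cohort_features(cohort, config, progress = progress)
  ft <- cf$features
  ok <- !is.na(ft$nuclei_median)
  ft <- ft[ok, , drop = FALSE]
  x <- as.matrix(ft[, c("nuclei_median", "nuclei_min", "nuclei_max",
                        "nuclei_count", "vessel_median", "vessel_min",
                        "vessel_max", "vessel_count")])
  cascade <- fd_cascade(x, ft$true_image_label, ft$case_id,
                        ft$true_case_label,
                        hidden = config$ann$hidden,
                        learning_rate = config$ann$learning_rate,
                        max_epochs = config$ann$max_epochs,
                        patience = config$ann$patience,
                        batch_size = config$ann$batch_size,
                        seed = config$seed)

  case_results <- predict(cascade, x, ft$case_id)
  truth_case <- ft$true_case_label[match(names(case_results),
                                         as.character(ft$case_id))]
  pred_case <- vapply(case_results, `[[`, "", "final_case_label")
  case_levels <- c("HCC", "LM", "benign")
  case_cm <- confusion_matrix(pred_case, truth_case,
                              labels = intersect(case_levels,
                                                 union(pred_case, truth_case)))

  # image-level 3-class assignment: benign image -> normal, malignant
  # image -> the case's final label
  img_pred <- character(nrow(ft))
  for (cs in names(case_results)) {
    sel <- as.character(ft$case_id) == cs
    res <- case_results[[cs]]
    img_pred[sel] <- ifelse(res$malignant_flags,
                            res$final_case_label, "normal")
  }
  img_truth <- ifelse(ft$true_image_label == "tumor",
                      ft$true_case_label, "normal")
  img_levels <- intersect(c("HCC", "LM", "benign", "normal"),
                          union(img_pred, img_truth))
  img_cm <- confusion_matrix(img_pred, img_truth, labels = img_levels)
  img_kappa <- cohen_kappa(img_cm)

  out <- list(features = cf$features, seg_quality = cf$seg_quality,
              cascade = cascade,
              stage1_test_accuracy = cascade$stage1$test$accuracy,
              case_results = case_results,
              case_confusion = case_cm,
              case_accuracy = sum(diag(case_cm)) / sum(case_cm),
              image_confusion = img_cm, image_kappa = img_kappa)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_artifact(cf$features, file.path(out_dir, "features.csv"),
                       config)
    write.csv(as.data.frame(case_cm),
              file.path(out_dir, "case_confusion.csv"))
    write.csv(as.data.frame(img_cm),
              file.path(out_dir, "image_confusion.csv"))
    write_kappa_csv(list(system_vs_truth = img_kappa),
                    file.path(out_dir, "kappa.csv"))
    write_fdnn(cascade$stage1, file.path(out_dir, "stage1.json"))
    write_fdnn(cascade$stage2, file.path(out_dir, "stage2.json"))
  }
  out
}
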