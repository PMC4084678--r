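# Colour-threshold segmentation of histology images in HSV space.
#
# Images are numeric arrays height x width x 3. RGB channels are fractions
# in [0, 1] (the convention of png::readPNG); HSV planes are hue in degrees
# [0, 360), saturation and value as fractions in [0, 1]. Coordinates are
# 1-based (row, col) with the origin at the top-left pixel, as usual in R.

#' Convert an RGB image to HSV
#'
#' Applies the standard hexcone RGB-to-HSV transform pixelwise. Hue-based
#' thresholds separate the blue hematoxylin-stained nuclei and the brown
#' DAB-developed (CD31/CD34) vessel signal far more cleanly than any box in
#' RGB space, because stain identity lives almost entirely in hue.
#'
#' @param img numeric array `h x w x 3`, RGB fractions in \[0, 1\].
#' @return numeric array `h x w x 3`: hue in degrees \[0, 360), saturation
#'   and value in \[0, 1\].
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))  # pure red
#' rgb_to_hsv(px)[1, 1, ]                     # hue 0, sat 1, val 1
#' @export
rgb_to_hsv <- function(img) {
  check_rgb(img)
  d <- dim(img)
  flat <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

#' Flatten the value channel of an HSV image
#'
#' Sets every pixel's value (brightness) component to a constant, collapsing
#' the colour space to the hue-saturation plane. Stain intensity varies with
#' section thickness and illumination; discarding brightness makes the
#' subsequent thresholds depend only on chromatic identity.
#'
#' @param hsv numeric array `h x w x 3` as returned by [rgb_to_hsv()].
#' @param value constant brightness in \[0, 1\]; default 1.
#' @return the image with `hsv[, , 3]` set to `value`; hue and saturation
#'   are untouched. Idempotent.
#' @export
flatten_value <- function(hsv, value = 1) {
  check_hsv(hsv)
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1)
    stopf("`value` must be a single number in [0, 1]")
  hsv[, , 3] <- value
  hsv
}

#' Describe one colour channel to segment
#'
#' A channel is a hue interval plus a saturation floor: a pixel belongs to
#' the channel when its circular hue distance to `reference_hue` is at most
#' `hue_tolerance` and its saturation is at least `min_saturation`.
#'
#' @param reference_hue centre of the hue interval, degrees.
#' @param hue_tolerance half-width of the interval, degrees in \[0, 180\].
#' @param min_saturation minimum saturation, fraction in \[0, 1\].
#' @param name channel label, e.g. `"nuclei"` or `"vessels"`.
#' @return an object of class `"channel_spec"`.
#' @seealso [default_channel_specs()] for the shipped nuclei/vessel values.
#' @export
channel_spec <- function(reference_hue, hue_tolerance, min_saturation,
                         name = "channel") {
  if (hue_tolerance < 0 || hue_tolerance > 180)
    stopf("`hue_tolerance` must be in [0, 180] degrees")
  if (min_saturation < 0 || min_saturation > 1)
    stopf("`min_saturation` must be in [0, 1]")
  structure(list(reference_hue = (reference_hue %% 360),
                 hue_tolerance = hue_tolerance,
                 min_saturation = min_saturation,
                 name = name),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("channel '%s': hue %g deg +/- %g, saturation >= %g\n",
              x$name, x$reference_hue, x$hue_tolerance, x$min_saturation))
  invisible(x)
}

#' Default channel thresholds for nuclei and vessels
#'
#' Hematoxylin renders nuclei blue (hue near 240 degrees) and the DAB
#' chromogen renders CD31/CD34-positive endothelium brown (hue near 25
#' degrees). The background is nearly achromatic, so a saturation floor of
#' 0.25 removes it. Real slides need per-batch tuning; these defaults are
#' matched to the synthetic generator's palette.
#'
#' @return named list of two [channel_spec()] objects, `nuclei` and
#'   `vessels`.
#' @export
default_channel_specs <- function() {
  list(nuclei  = channel_spec(240, 35, 0.25, "nuclei"),
       vessels = channel_spec(25, 35, 0.25, "vessels"))
}

#' Circular distance between hues
#'
#' @param h1,h2 hues in degrees (vectorized, recycled).
#' @return distance in degrees, in \[0, 180\]; symmetric in its arguments.
#' @export
hue_distance <- function(h1, h2) {
  d <- abs((h1 %% 360) - (h2 %% 360))
  pmin(d, 360 - d)
}

#' Threshold one colour channel of an HSV image
#'
#' @param hsv flattened HSV image (see [flatten_value()]; the value plane is
#'   ignored by the predicate either way).
#' @param spec a [channel_spec()].
#' @return logical matrix `h x w`; `TRUE` where the pixel satisfies both the
#'   hue-interval and the saturation predicate.
#' @export
segment_channel <- function(hsv, spec) {
  check_hsv(hsv)
  stopifnot(inherits(spec, "channel_spec"))
  hue_ok <- hue_distance(hsv[, , 1], spec$reference_hue) <= spec$hue_tolerance
  sat_ok <- hsv[, , 2] >= spec$min_saturation
  mask <- hue_ok & sat_ok
  dim(mask) <- dim(hsv)[1:2]
  mask
}

#' Extract connected elements from a binary mask
#'
#' Labels connected components, discards those smaller than `min_pixels`
#' (sub-resolution specks are stain debris, not nuclei or vessels), and
#' optionally discards components touching the image border, whose shape --
#' and therefore fractal dimension -- is truncated by the field of view.
#'
#' @param mask logical matrix.
#' @param min_pixels minimum component size kept; default 10.
#' @param exclude_border drop components with any pixel on the first/last
#'   row or column. Recommended for nuclei (incomplete nuclei bias the FD);
#'   usually off for vessels, which legitimately cross the field.
#' @param connectivity 8 (default) or 4.
#' @return list of elements, in row-major scan order of each component's
#'   first pixel. Each element is a list with `element_id`, `pixels` (an
#'   `n x 2` matrix of 1-based (row, col) coordinates), `pixel_count` and
#'   `touches_border`.
#' @export
extract_elements <- function(mask, min_pixels = 10, exclude_border = FALSE,
                             connectivity = 8) {
  check_mask(mask)
  if (!connectivity %in% c(4, 8)) stopf("`connectivity` must be 4 or 8")
  if (min_pixels < 1) stopf("`min_pixels` must be >= 1")
  if (!any(mask)) return(list())
  lab <- label_components_cpp(mask, as.integer(connectivity))
  nlab <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  border <- logical(nlab)
  nr <- nrow(mask); nc <- ncol(mask)
  edge <- c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])
  border[unique(edge[edge > 0L])] <- TRUE

  keep <- which(sizes >= min_pixels & !(exclude_border & border))
  out <- vector("list", length(keep))
  idx <- which(lab > 0L)
  grp <- split(idx, lab[idx])           # names are label ids
  for (k in seq_along(keep)) {
    id <- keep[k]
    px <- grp[[as.character(id)]]
    out[[k]] <- list(
      element_id = id,
      pixels = cbind(row = ((px - 1L) %% nr) + 1L,
                     col = ((px - 1L) %/% nr) + 1L),
      pixel_count = sizes[id],
      touches_border = border[id])
  }
  out
}

#' Apply manual corrections to a mask
#'
#' Semi-automatic workflows let an operator repair threshold failures --
#' adding under-selected element pixels and removing over-selected debris --
#' before fractal dimensions are computed. This is the scripted equivalent:
#' a pure set edit on the mask.
#'
#' @param mask logical matrix.
#' @param add,remove `n x 2` matrices of 1-based (row, col) coordinates (or
#'   `NULL`). The two sets must be disjoint and within bounds.
#' @return the edited mask: `(mask union add) minus remove`.
#' @export
manual_override <- function(mask, add = NULL, remove = NULL) {
  check_mask(mask)
  as_idx <- function(coords, what) {
    if (is.null(coords) || NROW(coords) == 0) return(integer(0))
    coords <- matrix(as.integer(coords), ncol = 2)
    if (any(coords[, 1] < 1 | coords[, 1] > nrow(mask) |
            coords[, 2] < 1 | coords[, 2] > ncol(mask)))
      stopf("`%s` contains out-of-bounds coordinates", what)
    (coords[, 2] - 1L) * nrow(mask) + coords[, 1]
  }
  ia <- as_idx(add, "add"); ir <- as_idx(remove, "remove")
  if (length(intersect(ia, ir)) > 0)
    stopf("`add` and `remove` must be disjoint")
  mask[ia] <- TRUE
  mask[ir] <- FALSE
  mask
}

# ---- argument checks ------------------------------------------------------

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("expected an RGB array of dimension h x w x 3")
  if (dim(img)[1] < 1 || dim(img)[2] < 1) stopf("image has empty dimensions")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stopf("RGB values must be fractions in [0, 1]")
  invisible(img)
}

check_hsv <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("expected an HSV array of dimension h x w x 3")
  if (dim(img)[1] < 1 || dim(img)[2] < 1) stopf("image has empty dimensions")
  invisible(img)
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("expected a logical matrix mask")
  if (anyNA(mask)) stopf("mask contains NA")
  invisible(mask)
}
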