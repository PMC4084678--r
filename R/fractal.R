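# Box-counting (Minkowski-Bouligand / Hausdorff-style) fractal dimension of
# binary rasters.
#
# The estimator follows the classic dyadic scheme: pad the mask to a square
# whose side is a power of 2, count the occupied cells N(e) of grids with
# box size e = side, side/2, ..., 1, and take the least-squares slope of
# log N(e) against log(1/e). For the power-law N(e) = C * e^(-FD) that slope
# is the dimension FD. Regressing on log(1/e) rather than log(e) flips the
# sign so FD is reported positive, between 0 (isolated point) and 2 (filled
# plane region).

#' Pad a mask to a power-of-two square
#'
#' @param mask logical matrix with at least one row and column.
#' @return square logical matrix of side `2^k`, the smallest power of two
#'   at least `max(dim(mask))`; the input occupies the top-left corner and
#'   padding pixels are `FALSE` (background).
#' @export
pad_to_pow2 <- function(mask) {
  check_mask(mask)
  side <- 2L^ceiling(log2(max(dim(mask), 1L)))
  if (nrow(mask) == side && ncol(mask) == side) return(mask)
  out <- matrix(FALSE, side, side)
  out[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  out
}

#' Count occupied boxes at one scale
#'
#' Counts the axis-aligned `e x e` grid cells (grid anchored at the image
#' origin) that contain at least one `TRUE` pixel.
#'
#' @param mask square logical matrix whose side is a power of 2.
#' @param e box size in pixels; must divide the side.
#' @return integer count.
#' @export
box_count <- function(mask, e) {
  check_mask(mask)
  side <- nrow(mask)
  if (ncol(mask) != side) stopf("mask must be square; use pad_to_pow2()")
  if (e < 1 || side %% e != 0) stopf("box size %s does not divide side %s", e, side)
  if (e == 1) return(sum(mask))
  grid_r <- (seq_len(side) - 1L) %/% e
  grid_c <- (seq_len(side) - 1L) %/% e
  occ <- rowsum(mask + 0L, grid_r, reorder = TRUE)        # collapse rows
  occ <- t(rowsum(t(occ), grid_c, reorder = TRUE))        # collapse cols
  sum(occ > 0L)
}

#' Box counts at every dyadic scale
#'
#' Evaluates N(e) for e = side, side/2, ..., 1 by repeated 2x2 OR-reduction
#' of the mask, which visits each pixel O(1) times in total.
#'
#' @param mask square logical matrix, power-of-two side (see
#'   [pad_to_pow2()]).
#' @return list with `e` (box sizes, descending from the side to 1) and
#'   `n` (occupied-box counts `N(e)`).
#' @keywords internal
box_count_series <- function(mask) {
  check_mask(mask)
  side <- nrow(mask)
  if (ncol(mask) != side || bitwAnd(side, side - 1L) != 0L)
    stopf("mask must be square with power-of-2 side")
  e <- 1L
  es <- integer(0); ns <- integer(0)
  m <- mask
  repeat {
    es <- c(es, e); ns <- c(ns, sum(m))
    if (nrow(m) == 1L) break
    h <- nrow(m) %/% 2L
    odd <- seq(1L, 2L * h, by = 2L)
    m <- m[odd, , drop = FALSE] | m[odd + 1L, , drop = FALSE]
    m <- m[, odd, drop = FALSE] | m[, odd + 1L, drop = FALSE]
    e <- e * 2L
  }
  ord <- rev(seq_along(es))
  list(e = es[ord], n = ns[ord])
}

#' Box-counting fractal dimension of a binary mask
#'
#' Pads the mask (see [pad_to_pow2()]), counts occupied boxes over the full
#' dyadic scale range down to single pixels, and fits a least-squares line
#' to the points `(log(1/e), log N(e))`. The slope is the dimension
#' estimate. For a finite raster the estimate is bounded by 0 and 2; masks
#' offering fewer than two distinct scales (a 1x1 mask) get FD 0 by
#' convention.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return object of class `"fd_result"`: a list with `fd` (the slope),
#'   `fit_points` (data frame `log_inv_e`, `log_n`, plus `e` and `n`), and
#'   `residual_rms` (root-mean-square residual of the fit, a goodness-of-fit
#'   diagnostic: 0 for exact power laws).
#' @examples
#' full <- matrix(TRUE, 64, 64)
#' box_counting_fd(full)$fd   # exactly 2
#' @export
box_counting_fd <- function(mask) {
  check_mask(mask)
  if (!any(mask))
    stopf("fractal dimension is undefined for an empty mask")
  s <- box_count_series(pad_to_pow2(mask))
  pts <- data.frame(log_inv_e = log(1 / s$e), log_n = log(s$n),
                    e = s$e, n = s$n)
  if (nrow(pts) < 2) {
    fd <- 0; rms <- 0
  } else {
    fit <- lm.fit(cbind(1, pts$log_inv_e), pts$log_n)
    fd <- unname(fit$coefficients[2])
    rms <- sqrt(mean(fit$residuals^2))
  }
  structure(list(fd = fd, fit_points = pts, residual_rms = rms),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("box-counting FD = %.4f (%d scales, residual RMS %.4g)\n",
              x$fd, nrow(x$fit_points), x$residual_rms))
  invisible(x)
}

#' Fractal dimension of one segmented element
#'
#' Rasterizes the element's pixel set onto its tight bounding box and
#' applies [box_counting_fd()], so the estimate depends only on the
#' element's shape, not on where it sits in the field.
#'
#' By default the dimension is computed on the element's boundary contour
#' (the pixels with at least one 4-neighbour outside the element). The
#' morphometric quantity of interest is the irregularity of the perimeter
#' line of a nucleus or vessel outline: a smooth outline measures near 1,
#' a convoluted one approaches 2, which is also the only reading on which
#' small smooth elements can score near 1 (the filled measurement of any
#' compact blob tens of pixels across is ~1.6-1.9 whatever its contour
#' looks like, because it is dominated by area scaling). Set
#' `contour = FALSE` to measure the filled pixel set instead.
#'
#' @param element one element from [extract_elements()] (anything with a
#'   `pixels` matrix of (row, col) coordinates).
#' @param contour measure the boundary contour (default) or the filled
#'   set.
#' @return an `"fd_result"` (see [box_counting_fd()]). A single-pixel
#'   element has FD 0 either way.
#' @export
element_fd <- function(element, contour = TRUE) {
  px <- element$pixels
  if (is.null(px) || nrow(px) == 0) stopf("element has no pixels")
  r <- px[, 1] - min(px[, 1]) + 1L
  c_ <- px[, 2] - min(px[, 2]) + 1L
  m <- matrix(FALSE, max(r), max(c_))
  m[cbind(r, c_)] <- TRUE
  if (contour) m <- contour_mask(m)
  box_counting_fd(m)
}

# Boundary pixels of a mask: foreground with at least one 4-neighbour that
# is background (pixels on the raster edge border background by definition).
contour_mask <- function(m) {
  nr <- nrow(m) + 2L; nc <- ncol(m) + 2L
  p <- matrix(FALSE, nr, nc)
  p[2:(nr - 1L), 2:(nc - 1L)] <- m
  core <- p[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  interior <- p[1:(nr - 2L), 2:(nc - 1L), drop = FALSE] &
    p[3:nr, 2:(nc - 1L), drop = FALSE] &
    p[2:(nr - 1L), 1:(nc - 2L), drop = FALSE] &
    p[2:(nr - 1L), 3:nc, drop = FALSE]
  core & !interior
}

#' Fractal dimensions for a list of elements
#'
#' @param elements output of [extract_elements()].
#' @param channel label recorded in the output.
#' @param case_id,slide_id,image_id identifiers recorded in the output.
#' @param contour passed to [element_fd()].
#' @return data frame with one row per element: `case_id`, `slide_id`,
#'   `image_id`, `channel`, `element_id`, `pixel_count`, `fd`. This is the
#'   long ("batch") layout written to CSV by the pipeline.
#' @export
element_fd_table <- function(elements, channel = "nuclei", case_id = NA,
                             slide_id = NA, image_id = NA, contour = TRUE) {
  n <- length(elements)
  data.frame(
    case_id = rep(case_id, n), slide_id = rep(slide_id, n),
    image_id = rep(image_id, n), channel = rep(channel, n),
    element_id = if (n) vapply(elements, `[[`, 0L, "element_id") else integer(0),
    pixel_count = if (n) vapply(elements, `[[`, 0L, "pixel_count") else integer(0),
    fd = if (n) vapply(elements, function(el) element_fd(el, contour)$fd, 0)
         else numeric(0),
    stringsAsFactors = FALSE)
}
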