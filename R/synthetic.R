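# Synthetic inputs: canonical fractal fixtures with known dimension (the
# oracle set for the box-counting estimator) and a seeded generator of
# histology-like RGB cohorts with ground-truth masks, so the whole
# segmentation -> FD -> classification pipeline can be exercised without
# patient images.

# ---- canonical fractal fixtures ------------------------------------------

#' Deterministic fractal test masks with known dimension
#'
#' Constructs standard sets whose limiting box-counting dimension is known
#' in closed form, for validating the estimator: `filled_square` (FD 2),
#' `line` (FD 1), `single_pixel` (FD 0), `sierpinski_triangle`
#' (log 3 / log 2, side `2^order`), `sierpinski_carpet` (log 8 / log 3,
#' side `3^order`) and `koch_outline` (log 4 / log 3, a von Koch curve
#' rasterized on a `side`-pixel-wide canvas).
#'
#' @param kind one of the names above.
#' @param order iteration depth for the recursive sets.
#' @param side canvas side in pixels for the non-recursive kinds (and the
#'   Koch curve); the Sierpinski sets fix their own side from `order`.
#' @return logical mask with attribute `theoretical_fd`.
#' @examples
#' m <- fractal_fixture("sierpinski_triangle", order = 5)
#' sum(m)  # 3^5 pixels
#' @export
fractal_fixture <- function(kind = c("filled_square", "line", "single_pixel",
                                     "sierpinski_triangle",
                                     "sierpinski_carpet", "koch_outline"),
                            order = 4, side = 64) {
  kind <- match.arg(kind)
  mask <- switch(kind,
    filled_square = matrix(TRUE, side, side),
    line = {
      m <- matrix(FALSE, side, side)
      m[max(1L, side %/% 2L), ] <- TRUE
      m
    },
    single_pixel = {
      m <- matrix(FALSE, side, side)
      m[max(1L, side %/% 2L), max(1L, side %/% 2L)] <- TRUE
      m
    },
    sierpinski_triangle = {
      s <- 2L^order
      idx <- 0:(s - 1L)
      outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
    },
    sierpinski_carpet = {
      s <- 3L^order
      keep <- function(v) {   # TRUE where no base-3 digit equals 1 jointly
        d <- matrix(0L, length(v), order)
        x <- v
        for (k in seq_len(order)) { d[, k] <- x %% 3L; x <- x %/% 3L }
        d
      }
      di <- keep(0:(s - 1L)); dj <- keep(0:(s - 1L))
      m <- matrix(TRUE, s, s)
      for (k in seq_len(order))
        m <- m & !outer(di[, k] == 1L, dj[, k] == 1L, "&")
      m
    },
    koch_outline = koch_mask(order, side))
  fd0 <- c(filled_square = 2, line = 1, single_pixel = 0,
           sierpinski_triangle = log(3) / log(2),
           sierpinski_carpet = log(8) / log(3),
           koch_outline = log(4) / log(3))[[kind]]
  attr(mask, "theoretical_fd") <- fd0
  mask
}

# von Koch curve: recursive subdivision of a horizontal segment, rasterized
# by dense sampling of each final segment.
koch_mask <- function(order, side) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (k in seq_len(order)) {
    out <- matrix(0, nrow = (nrow(pts) - 1) * 4 + 1, ncol = 2)
    n <- 0
    for (i in seq_len(nrow(pts) - 1)) {
      p <- pts[i, ]; q <- pts[i + 1, ]
      d <- (q - p) / 3
      peak <- p + d + c(d[1] * cos(-pi / 3) - d[2] * sin(-pi / 3),
                        d[1] * sin(-pi / 3) + d[2] * cos(-pi / 3))
      seg <- rbind(p, p + d, peak, p + 2 * d)
      out[n + 1:4, ] <- seg
      n <- n + 4
    }
    out[n + 1, ] <- pts[nrow(pts), ]
    pts <- out
  }
  # scale to the canvas; the curve's height is sqrt(3)/6 of its base
  sc <- (side - 2) / 1
  x <- pts[, 1] * sc + 1
  y <- pts[, 2] * sc
  m <- matrix(FALSE, max(3L, ceiling(max(-y)) + 3L), side)
  for (i in seq_len(nrow(pts) - 1)) {
    nstep <- max(2L, ceiling(max(abs(x[i + 1] - x[i]),
                                 abs(y[i + 1] - y[i]))) * 2L)
    t <- seq(0, 1, length.out = nstep)
    rr <- pmin(nrow(m), pmax(1L, round(-((1 - t) * y[i] + t * y[i + 1])) + 2L))
    cc <- pmin(ncol(m), pmax(1L, round((1 - t) * x[i] + t * x[i + 1])))
    m[cbind(rr, cc)] <- TRUE
  }
  m
}

# ---- element renderers ----------------------------------------------------

#' Render one nucleus as a randomly perturbed disk
#'
#' The boundary is `r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k))`
#' with random phases, octave-spaced wave numbers `k = 2, 4, 8, ...` up to
#' roughly `pi * R` (wiggles down to about two pixels' wavelength), and
#' amplitudes proportional to `k` -- fine-scale displacement dominates --
#' normalised so their absolute sum equals `roughness`; the interior is
#' filled. Roughness 0 gives a discrete disk, whose contour measures near
#' FD 1; increasing roughness convolutes the perimeter at every scale and
#' raises its box-counting dimension monotonically. This contour-roughness
#' knob is what separates the simulated tissue classes, emulating the
#' pleomorphic, irregularly contoured nuclei of malignant tissue. A
#' flat or `1/k` amplitude spectrum does not work here: it perturbs the
#' shape only at coarse scales and leaves the contour dimension flat.
#'
#' @param center (row, col) of the nucleus centre.
#' @param mean_radius mean radius R in pixels (>= 2).
#' @param roughness total relative boundary perturbation, in \[0, 0.6\].
#' @param n_octaves number of harmonics; default every octave from wave
#'   number 2 up to `pi * mean_radius`.
#' @param seed optional; when given, the draw is made under this seed and
#'   the caller's RNG state is untouched, otherwise the current RNG stream
#'   is used.
#' @return `n x 2` integer matrix of (row, col) pixel coordinates.
#' @export
render_nucleus <- function(center, mean_radius, roughness, n_octaves = NULL,
                           seed = NULL) {
  if (mean_radius < 2) stopf("`mean_radius` must be >= 2 pixels")
  if (roughness < 0 || roughness > 0.6)
    stopf("`roughness` must be in [0, 0.6] to keep the radius positive")
  draw <- function() {
    jmax <- max(2L, floor(log2(pi * mean_radius)))
    if (!is.null(n_octaves)) jmax <- min(jmax, n_octaves + 1L)
    k <- 2^(1:jmax)
    raw <- k * runif(length(k), 0.6, 1)
    a <- if (roughness > 0) roughness * raw / sum(raw) else raw * 0
    phi <- runif(length(k), 0, 2 * pi)
    list(a = a, phi = phi, k = k)
  }
  h <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rmax <- mean_radius * (1 + roughness) + 1
  off <- seq(-ceiling(rmax), ceiling(rmax))
  dr <- matrix(off, length(off), length(off))
  dc <- t(dr)
  theta <- atan2(dc, dr)
  rad <- sqrt(dr^2 + dc^2)
  bound <- mean_radius *
    (1 + Reduce(`+`, lapply(seq_along(h$k), function(i)
      h$a[i] * cos(h$k[i] * theta + h$phi[i]))))
  inside <- rad <= bound
  cbind(row = center[1] + dr[inside], col = center[2] + dc[inside])
}

#' Render one vessel as a dilated random-walk centreline
#'
#' The centreline is a constant-speed random walk whose heading receives a
#' Gaussian increment with standard deviation `tortuosity` (radians) at
#' each step; the walk is dilated to the requested thickness by stamping a
#' disk at every step. With probability `branch_prob` per step a daughter
#' branch of half the remaining length forks off, mimicking sprouting
#' microvessels. Tortuosity 0 and no branching give a straight segment.
#'
#' @param start (row, col) starting point.
#' @param n_steps number of unit steps in the centreline.
#' @param thickness vessel calibre in pixels (diameter).
#' @param tortuosity heading-change standard deviation per step, radians.
#' @param branch_prob per-step probability of spawning a branch; default 0.
#' @param bounds (rows, cols) of the image; the walk reflects off the
#'   bounds so vessels stay mostly in the field.
#' @param seed optional seed, as in [render_nucleus()].
#' @param heading initial heading in radians; drawn uniformly when `NULL`.
#' @return `n x 2` integer matrix of (row, col) pixel coordinates.
#' @export
render_vessel <- function(start, n_steps, thickness, tortuosity,
                          branch_prob = 0, bounds = c(512, 512),
                          seed = NULL, heading = NULL) {
  if (n_steps < 2) stopf("`n_steps` must be >= 2")
  rad <- max(0, (thickness - 1) / 2)
  doff <- expand.grid(dr = seq(-ceiling(rad), ceiling(rad)),
                      dc = seq(-ceiling(rad), ceiling(rad)))
  doff <- doff[doff$dr^2 + doff$dc^2 <= (rad + 0.25)^2, , drop = FALSE]

  walk <- function(pos, ang, steps, depth) {
    out <- vector("list", 8)
    path <- matrix(0, steps + 1, 2)
    path[1, ] <- pos
    nb <- 0
    for (s in seq_len(steps)) {
      if (tortuosity > 0) ang <- ang + rnorm(1, 0, tortuosity)
      pos <- pos + c(cos(ang), sin(ang))
      # reflect off the field bounds
      for (d in 1:2) {
        if (pos[d] < 2) { pos[d] <- 4 - pos[d]; ang <- pi - ang + pi * (d == 1) }
        if (pos[d] > bounds[d] - 1) pos[d] <- 2 * (bounds[d] - 1) - pos[d]
      }
      path[s + 1, ] <- pos
      if (depth > 0 && branch_prob > 0 && s > 3 && runif(1) < branch_prob) {
        nb <- nb + 1
        out[[nb]] <- walk(pos, ang + sample(c(-1, 1), 1) * runif(1, 0.5, 1.2),
                          max(3L, (steps - s) %/% 2L), depth - 1)
      }
    }
    do.call(rbind, c(list(path), out[seq_len(nb)]))
  }
  build <- function() {
    ang <- if (is.null(heading)) runif(1, 0, 2 * pi) else heading
    walk(as.numeric(start), ang, n_steps, depth = 2L)
  }
  path <- if (is.null(seed)) build() else with_seed(seed, build())

  ctr <- unique(round(path))
  px <- cbind(rep(ctr[, 1], each = nrow(doff)) + doff$dr,
              rep(ctr[, 2], each = nrow(doff)) + doff$dc)
  px <- px[px[, 1] >= 1 & px[, 1] <= bounds[1] &
             px[, 2] >= 1 & px[, 2] <= bounds[2], , drop = FALSE]
  px <- unique(px)
  colnames(px) <- c("row", "col")
  px
}

# ---- cohort specification -------------------------------------------------

# Per-class rendering parameters. HCC tissue carries large pleomorphic
# (rough-contoured) nuclei and abundant tortuous, branching microvessels;
# metastases have intermediate nuclear atypia and a relative paucity of
# immunolabeled vessels; normal parenchyma has small smooth nuclei and
# sparse thin vessels. Boundary-roughness amplitudes are ordered
# HCC > LM > normal in both channels so the class-conditional FD
# distributions are ordered the same way.
default_class_params <- function() {
  list(
    HCC = list(n_nuclei = c(8, 14), nucleus_radius = c(22, 40),
               nucleus_roughness = 0.35,
               n_vessels = c(6, 9), vessel_thickness = c(3, 5),
               vessel_steps = c(120, 220), vessel_tortuosity = 0.45,
               vessel_branch_prob = 0.03),
    LM  = list(n_nuclei = c(10, 18), nucleus_radius = c(14, 26),
               nucleus_roughness = 0.16,
               n_vessels = c(2, 4), vessel_thickness = c(2, 3),
               vessel_steps = c(80, 150), vessel_tortuosity = 0.18,
               vessel_branch_prob = 0),
    normal = list(n_nuclei = c(15, 30), nucleus_radius = c(8, 14),
                  nucleus_roughness = 0.04,
                  n_vessels = c(1, 3), vessel_thickness = c(1, 2),
                  vessel_steps = c(60, 110), vessel_tortuosity = 0.06,
                  vessel_branch_prob = 0)
  )
}

#' Specify a synthetic cohort
#'
#' Describes a study-structured cohort: `n_cases` patients, half
#' hepatocellular carcinoma (HCC) and half liver metastasis (LM) by
#' default, each contributing 10 slides (5 tumour, 5 normal parenchyma)
#' with 10 images per slide. Tumour-slide images are rendered with the
#' case's class parameters, normal-slide images with the normal-tissue
#' parameters.
#'
#' @param n_cases number of cases; default 20.
#' @param case_classes character vector of `"HCC"`/`"LM"` per case;
#'   default alternates so classes are balanced.
#' @param slides_per_case total slides per case (half tumour, half
#'   normal); default 10.
#' @param images_per_slide default 10.
#' @param image_size side of the square images in pixels; default 512.
#' @param class_params per-class rendering parameters; see the package
#'   vignette. Defaults encode HCC > LM > normal boundary complexity.
#' @param seed root seed; every image is generated from a named substream
#'   of it, so any single image can be regenerated independently.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cases = 20, case_classes = NULL,
                        slides_per_case = 10, images_per_slide = 10,
                        image_size = 512,
                        class_params = default_class_params(),
                        seed = 1) {
  if (is.null(case_classes))
    case_classes <- rep(c("HCC", "LM"), length.out = n_cases)
  if (length(case_classes) != n_cases ||
      !all(case_classes %in% c("HCC", "LM")))
    stopf("`case_classes` must be %d values in {HCC, LM}", n_cases)
  if (slides_per_case %% 2 != 0) stopf("`slides_per_case` must be even")
  r <- vapply(class_params, `[[`, 0, "nucleus_roughness")
  if (!(r[["HCC"]] > r[["LM"]] && r[["LM"]] > r[["normal"]]))
    stopf("nucleus roughness must be ordered HCC > LM > normal")
  t_ <- vapply(class_params, `[[`, 0, "vessel_tortuosity")
  if (!(t_[["HCC"]] > t_[["LM"]] && t_[["LM"]] > t_[["normal"]]))
    stopf("vessel tortuosity must be ordered HCC > LM > normal")
  structure(list(n_cases = n_cases, case_classes = case_classes,
                 slides_per_case = slides_per_case,
                 images_per_slide = images_per_slide,
                 image_size = image_size, class_params = class_params,
                 seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d cases (%d HCC / %d LM), %d slides x %d images, %dpx, seed %d\n",
    x$n_cases, sum(x$case_classes == "HCC"), sum(x$case_classes == "LM"),
    x$slides_per_case, x$images_per_slide, x$image_size, x$seed))
  invisible(x)
}

# Stain-like palette. The background is a faint eosin pink with saturation
# well below the 0.25 threshold; nuclei sit in a narrow blue hue band and
# vessels in a brown band, both inside the default channel tolerances, so
# the shipped thresholds recover the ground truth exactly.
palette_hsv <- list(
  background = list(h = 340, s = 0.06, v = 0.97),
  nuclei = list(h = c(233, 247), s = c(0.70, 0.90), v = c(0.45, 0.65)),
  vessels = list(h = c(18, 32), s = c(0.65, 0.85), v = c(0.50, 0.70)))

hsv_to_rgb_triplet <- function(h, s, v) {
  as.vector(grDevices::col2rgb(grDevices::hsv(h / 360, s, v))) / 255
}

#' Render one synthetic histology image
#'
#' Draws a light background, then the nuclei (blue hues), then the vessels
#' (brown hues, over-painting where they cross nuclei), and returns the
#' image together with ground-truth masks that reflect the final pixel
#' ownership.
#'
#' @param spec a [cohort_spec()].
#' @param case_id,slide_id,image_id 1-based indices into the cohort
#'   structure; the image seed is a named substream of the root seed, so
#'   the same triple always yields the same image.
#' @return list with `rgb` (array `size x size x 3`), `nuclei_mask`,
#'   `vessels_mask` (logical matrices), `tissue` (`"HCC"`, `"LM"` or
#'   `"normal"`), `true_image_label` (`"tumor"`/`"normal"`) and
#'   `true_case_label`.
#' @export
generate_image <- function(spec, case_id, slide_id, image_id) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tumor <- spec$slides_per_case %/% 2L
  is_tumor <- slide_id <= n_tumor
  tissue <- if (is_tumor) spec$case_classes[case_id] else "normal"
  p <- spec$class_params[[tissue]]
  size <- spec$image_size
  seed <- derive_seed(spec$seed, "image", case_id, slide_id, image_id)

  with_seed(seed, {
    bg <- palette_hsv$background
    base <- hsv_to_rgb_triplet(bg$h, bg$s, bg$v)
    # per-channel planes, painted in place; assembled into the array once
    red <- matrix(base[1], size, size)
    grn <- matrix(base[2], size, size)
    blu <- matrix(base[3], size, size)
    nuc <- matrix(FALSE, size, size)
    ves <- matrix(FALSE, size, size)

    element_colour <- function(pal) {
      hsv_to_rgb_triplet(runif(1, pal$h[1], pal$h[2]),
                         runif(1, pal$s[1], pal$s[2]),
                         runif(1, pal$v[1], pal$v[2]))
    }

    # vessels first, nuclei on top: a crossing then fragments the sparse
    # vessel, not the nuclei, whose whole-contour complexity carries the
    # class signal
    n_ves <- sample(p$n_vessels[1]:p$n_vessels[2], 1)
    for (i in seq_len(n_ves)) {
      start <- round(runif(2, size * 0.1, size * 0.9))
      steps <- sample(p$vessel_steps[1]:p$vessel_steps[2], 1)
      thick <- runif(1, p$vessel_thickness[1], p$vessel_thickness[2])
      px <- render_vessel(start, steps, thick, p$vessel_tortuosity,
                          p$vessel_branch_prob, bounds = c(size, size))
      if (nrow(px) == 0) next
      lin <- (px[, 2] - 1L) * size + px[, 1]
      col <- element_colour(palette_hsv$vessels)
      ves[lin] <- TRUE
      red[lin] <- col[1]; grn[lin] <- col[2]; blu[lin] <- col[3]
    }

    n_nuc <- sample(p$n_nuclei[1]:p$n_nuclei[2], 1)
    # keep whole nuclei inside the field; cap so small test images work
    margin <- min(p$nucleus_radius[2] * 2 + 2, floor(size / 3))
    vpix <- which(ves, arr.ind = TRUE)
    for (i in seq_len(n_nuc)) {
      rad <- runif(1, p$nucleus_radius[1], p$nucleus_radius[2])
      rmax <- rad * (1 + p$nucleus_roughness) + 1
      # rejection-sample the centre so nuclei rarely overlap a vessel
      # (overlap would fragment it); fall back to overlap when crowded
      ctr <- round(runif(2, margin, size - margin))
      for (try in seq_len(25)) {
        if (nrow(vpix) == 0 ||
            min((vpix[, 1] - ctr[1])^2 + (vpix[, 2] - ctr[2])^2) > rmax^2)
          break
        ctr <- round(runif(2, margin, size - margin))
      }
      px <- render_nucleus(ctr, rad, p$nucleus_roughness)
      px <- px[px[, 1] >= 1 & px[, 1] <= size &
                 px[, 2] >= 1 & px[, 2] <= size, , drop = FALSE]
      if (nrow(px) == 0) next
      lin <- (px[, 2] - 1L) * size + px[, 1]
      col <- element_colour(palette_hsv$nuclei)
      nuc[lin] <- TRUE
      ves[lin] <- FALSE     # nuclei over-paint: ownership to nuclei
      red[lin] <- col[1]; grn[lin] <- col[2]; blu[lin] <- col[3]
    }

    list(rgb = array(c(red, grn, blu), dim = c(size, size, 3)),
         nuclei_mask = nuc, vessels_mask = ves,
         tissue = tissue,
         true_image_label = if (is_tumor) "tumor" else "normal",
         true_case_label = spec$case_classes[case_id])
  })
}

#' Generate a synthetic cohort
#'
#' Builds the cohort manifest and, optionally, writes every image and its
#' ground-truth masks to disk as PNG. The returned object always carries
#' an `image_fn(case_id, slide_id, image_id)` closure that regenerates any
#' single image deterministically, so pipelines can stream a large cohort
#' without holding it in memory or on disk.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory, or `NULL` (default) for a purely in-memory
#'   cohort. When given, images go to `dir/images/`, masks to
#'   `dir/masks/`, the manifest to `dir/manifest.csv` and the spec echo to
#'   `dir/cohort_spec.yaml`.
#' @return object of class `"synthetic_cohort"`: the `spec`, the
#'   `manifest` data frame (`case_id`, `slide_id`, `image_id`, `path`,
#'   `true_image_label`, `true_case_label`) and `image_fn`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(image_id = seq_len(spec$images_per_slide),
                      slide_id = seq_len(spec$slides_per_case),
                      case_id = seq_len(spec$n_cases))
  grid <- grid[, c("case_id", "slide_id", "image_id")]
  grid <- grid[order(grid$case_id, grid$slide_id, grid$image_id), ]
  rownames(grid) <- NULL
  n_tumor <- spec$slides_per_case %/% 2L
  manifest <- data.frame(
    grid,
    path = NA_character_,
    true_image_label = ifelse(grid$slide_id <= n_tumor, "tumor", "normal"),
    true_case_label = spec$case_classes[grid$case_id],
    stringsAsFactors = FALSE)

  image_fn <- function(case_id, slide_id, image_id)
    generate_image(spec, case_id, slide_id, image_id)

  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      r <- manifest[i, ]
      im <- image_fn(r$case_id, r$slide_id, r$image_id)
      stem <- sprintf("case%02d_slide%02d_img%02d",
                      r$case_id, r$slide_id, r$image_id)
      p <- file.path(dir, "images", paste0(stem, ".png"))
      png::writePNG(im$rgb, p)
      png::writePNG(im$nuclei_mask * 1,
                    file.path(dir, "masks", paste0(stem, "_nuclei.png")))
      png::writePNG(im$vessels_mask * 1,
                    file.path(dir, "masks", paste0(stem, "_vessels.png")))
      manifest$path[i] <- p
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    yaml::write_yaml(unclass(spec)[setdiff(names(spec), "class_params")],
                     file.path(dir, "cohort_spec.yaml"))
  }
  structure(list(spec = spec, manifest = manifest, image_fn = image_fn),
            class = "synthetic_cohort")
}

#' Calibrate nucleus roughness against a target median FD
#'
#' Bisects the roughness amplitude until the median box-counting FD of a
#' sample of rendered nuclei falls within `tol` of `target_fd`. Used once,
#' with the published HCC median nuclear FD as the target, to anchor the
#' default class parameters; it is exported so the calibration is
#' reproducible.
#'
#' @param target_fd target median FD.
#' @param radius_range nucleus radius range sampled uniformly.
#' @param n_nuclei sample size per evaluation; default 60.
#' @param tol convergence tolerance on the median FD; default 0.05.
#' @param seed seed for the nucleus sample.
#' @param max_iter bisection iterations; default 12.
#' @return list with `roughness`, `median_fd` and `iterations`.
#' @export
calibrate_roughness <- function(target_fd, radius_range = c(22, 40),
                                n_nuclei = 60, tol = 0.05, seed = 1,
                                max_iter = 12) {
  med_fd <- function(rough) {
    fds <- vapply(seq_len(n_nuclei), function(i) {
      s <- derive_seed(seed, "calib", round(rough * 1e6), i)
      rad <- with_seed(derive_seed(s, "rad"),
                       runif(1, radius_range[1], radius_range[2]))
      px <- render_nucleus(c(200, 200), rad, rough, seed = s)
      element_fd(list(pixels = px))$fd
    }, 0)
    median(fds)
  }
  lo <- 0; hi <- 0.6
  f_lo <- med_fd(lo); f_hi <- med_fd(hi)
  best <- if (abs(f_lo - target_fd) < abs(f_hi - target_fd))
    list(roughness = lo, median_fd = f_lo) else list(roughness = hi, median_fd = f_hi)
  it <- 0
  while (it < max_iter && abs(best$median_fd - target_fd) > tol) {
    it <- it + 1
    mid <- (lo + hi) / 2
    f_mid <- med_fd(mid)
    if (abs(f_mid - target_fd) < abs(best$median_fd - target_fd))
      best <- list(roughness = mid, median_fd = f_mid)
    # FD increases with roughness, so bisect on the sign of the error
    if (f_mid < target_fd) { lo <- mid } else { hi <- mid }
  }
  c(best, list(iterations = it))
}
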