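# Independent oracles and small fixture builders shared across tests.

# Naive box-count: scan every e x e grid cell with nested loops and test
# it for an object pixel. Deliberately unrelated to the package's
# OR-reduction implementation.
brute_box_count <- function(mask, e) {
  side <- nrow(mask)
  stopifnot(ncol(mask) == side, side %% e == 0)
  n <- 0L
  for (br in seq(1L, side, by = e))
    for (bc in seq(1L, side, by = e))
      if (any(mask[br:(br + e - 1L), bc:(bc + e - 1L)])) n <- n + 1L
  n
}

# Random logical mask with roughly `density` foreground.
random_mask <- function(nr, nc, density = 0.2) {
  matrix(runif(nr * nc) < density, nr, nc)
}

# A tiny cohort specification used by pipeline/synthetic tests: small
# images and elements so a case renders in milliseconds, with the same
# HCC > LM > normal complexity ordering as the default.
tiny_cohort_spec <- function(n_cases = 2, seed = 7, images_per_slide = 1,
                             slides_per_case = 2, image_size = 96) {
  params <- list(
    HCC = list(n_nuclei = c(3, 5), nucleus_radius = c(8, 12),
               nucleus_roughness = 0.35,
               n_vessels = c(1, 2), vessel_thickness = c(2, 3),
               vessel_steps = c(30, 50), vessel_tortuosity = 0.45,
               vessel_branch_prob = 0),
    LM = list(n_nuclei = c(3, 5), nucleus_radius = c(6, 9),
              nucleus_roughness = 0.16,
              n_vessels = c(1, 1), vessel_thickness = c(1, 2),
              vessel_steps = c(25, 40), vessel_tortuosity = 0.18,
              vessel_branch_prob = 0),
    normal = list(n_nuclei = c(4, 6), nucleus_radius = c(4, 6),
                  nucleus_roughness = 0.04,
                  n_vessels = c(1, 1), vessel_thickness = c(1, 1),
                  vessel_steps = c(20, 30), vessel_tortuosity = 0.06,
                  vessel_branch_prob = 0))
  cohort_spec(n_cases = n_cases, slides_per_case = slides_per_case,
              images_per_slide = images_per_slide,
              image_size = image_size, class_params = params, seed = seed)
}

# Linearly separable two-class feature set with an inter-class gap of
# at least 4 sample standard deviations.
separable_dataset <- function(n_per_class = 60, p = 4, gap = 8, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0, 1), n_per_class),
             matrix(rnorm(n_per_class * p, gap, 1), n_per_class))
  y <- rep(c("benign", "malignant"), each = n_per_class)
  list(x = x, y = y)
}

# Published interpretation count tables, re-oriented to this package's
# convention (rows = assigned label, columns = correct diagnosis). In the
# printed originals each row is one true diagnosis (1050 HCC, 1400 LM
# images and the normal images), so the printed rows become columns here.
pathologist1_table <- function() {
  m <- cbind(c(1046, 4, 0), c(22, 1378, 0), c(0, 0, 2450))
  dimnames(m) <- list(c("HCC", "LM", "normal"), c("HCC", "LM", "normal"))
  m
}
pathologist2_table <- function() {
  m <- cbind(c(1044, 6, 0), c(17, 1383, 0), c(0, 0, 2450))
  dimnames(m) <- list(c("HCC", "LM", "normal"), c("HCC", "LM", "normal"))
  m
}
ann_system_table <- function() {
  m <- cbind(c(947, 103, 0), c(185, 1215, 0), c(27, 30, 2403))
  dimnames(m) <- list(c("HCC", "LM", "normal"), c("HCC", "LM", "normal"))
  m
}
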