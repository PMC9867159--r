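#' Foot geometry for synthetic thermograms
#'
#' Describes the synthetic foot silhouette and the proportional cuts that
#' divide it into the four plantar angiosomes. The silhouette is an
#' ellipse inscribed in the grid; the horizontal (calcaneal) cut sits at
#' 60% of foot height, separating the plantar arteries (MPA/LPA, upper
#' 60%) from the calcaneal arteries (MCA/LCA, lower 40%); the medial /
#' lateral split is a vertical cut at `sagittal_cut` of foot width,
#' mirrored between left and right feet.
#'
#' @param height_px,width_px Grid dimensions in pixels (positive).
#' @param coronal_cut Proportional height of the plantar/calcaneal cut
#'   (default 0.6).
#' @param sagittal_cut Proportional width of the medial/lateral cut
#'   (default 0.5).
#' @return A `foot_geometry` list.
#' @export
foot_geometry <- function(height_px = 100L, width_px = 60L,
                          coronal_cut = 0.6, sagittal_cut = 0.5) {
  stopifnot(height_px >= 1, width_px >= 1,
            coronal_cut > 0, coronal_cut < 1,
            sagittal_cut > 0, sagittal_cut < 1)
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 coronal_cut = coronal_cut, sagittal_cut = sagittal_cut),
            class = "foot_geometry")
}

#' Build an angiosome label mask
#'
#' Rasterizes the foot silhouette and labels every foot pixel with its
#' angiosome. Rows above the coronal cut (measured from the top of the
#' foot) belong to the plantar arteries, rows below to the calcaneal
#' arteries; columns on the medial side of the sagittal cut get the medial
#' labels. For a left foot the medial side is the right half of the image;
#' the right foot is its mirror image.
#'
#' @param geometry A [foot_geometry()].
#' @param side `"L"` or `"R"`.
#' @return Integer matrix (`height_px` x `width_px`) with labels 0
#'   background, 1 MPA, 2 LPA, 3 MCA, 4 LCA.
#' @export
make_foot_mask <- function(geometry, side = c("L", "R")) {
  side <- match.arg(side)
  h <- geometry$height_px
  w <- geometry$width_px
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  ry <- h / 2
  rx <- w / 2
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
  if (!any(inside)) stop("degenerate geometry: no foot pixels")

  foot_rows <- range(row[inside])
  foot_cols <- range(col[inside])
  # coronal cut at 60% of foot height from the toes (top of the image)
  cut_row <- foot_rows[1] + geometry$coronal_cut * (foot_rows[2] - foot_rows[1])
  cut_col <- foot_cols[1] + geometry$sagittal_cut * (foot_cols[2] - foot_cols[1])

  plantar <- row <= cut_row
  medial <- if (side == "L") col > cut_col else col <= cut_col

  mask <- matrix(0L, h, w)
  mask[inside & plantar & medial] <- REGION_CODES[["MPA"]]
  mask[inside & plantar & !medial] <- REGION_CODES[["LPA"]]
  mask[inside & !plantar & medial] <- REGION_CODES[["MCA"]]
  mask[inside & !plantar & !medial] <- REGION_CODES[["LCA"]]

  counts <- tabulate(mask[mask > 0L], nbins = 4L)
  if (any(counts == 0L)) {
    stop("degenerate geometry: angiosome region(s) ",
         paste(ANGIOSOMES[counts == 0L], collapse = ", "),
         " would be empty; increase the grid size")
  }
  mask
}

# Smooth low-frequency random field: coarse white noise bilinearly
# upsampled to the full grid, scaled to unit sd.
smooth_field <- function(h, w, coarse = c(6L, 4L)) {
  cz <- matrix(stats::rnorm(coarse[1] * coarse[2]), coarse[1], coarse[2])
  ry <- seq(1, coarse[1], length.out = h)
  rx <- seq(1, coarse[2], length.out = w)
  y0 <- pmin(floor(ry), coarse[1] - 1L)
  x0 <- pmin(floor(rx), coarse[2] - 1L)
  fy <- ry - y0
  fx <- rx - x0
  a <- cz[cbind(rep(y0, w), rep(x0, each = h))]
  b <- cz[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- cz[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- cz[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  wy <- rep(fy, w)
  wx <- rep(fx, each = h)
  f <- matrix((1 - wy) * (1 - wx) * a + wy * (1 - wx) * b +
                (1 - wy) * wx * cc + wy * wx * d, h, w)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f - mean(f)
}

TEMP_RANGE <- c(18, 37)

#' Generate a synthetic subject
#'
#' Draws one synthetic subject: both feet carry a smooth spatial
#' temperature field whose foot-wide mean follows the published class
#' distribution (diabetic 30.2 +/- 1.3 C, healthy 26.8 +/- 1.8 C).
#' Diabetic feet additionally receive 0-3 localized hot-spot blobs of
#' +1.5 to +3 C. All temperatures are clipped to \[18, 37).
#'
#' @param label `"healthy"` or `"diabetic"`.
#' @param geometry A [foot_geometry()].
#' @param seed Integer seed; the subject is a pure function of it.
#' @param noise_sd Within-foot spatial texture amplitude in Celsius
#'   (default 0.8).
#' @param hot_spot_range Hot-spot amplitude range in Celsius.
#' @param id Subject id stored in the record.
#' @return A subject record: list with `id`, `label`, `seed`, `left`,
#'   `right`; each foot a list with `grid` and `mask`.
#' @export
make_subject <- function(label = c("healthy", "diabetic"),
                         geometry = foot_geometry(), seed = 1L,
                         noise_sd = 0.8, hot_spot_range = c(1.5, 3),
                         id = sprintf("S%06d", seed)) {
  label <- match.arg(label)
  set.seed(seed)
  params <- if (label == "diabetic") c(30.2, 1.3) else c(26.8, 1.8)
  feet <- lapply(c("L", "R"), function(side) {
    mask <- make_foot_mask(geometry, side)
    base <- stats::rnorm(1, params[1], params[2])
    grid <- base + noise_sd * smooth_field(geometry$height_px, geometry$width_px)
    if (label == "diabetic") {
      n_spots <- sample.int(4L, 1L) - 1L  # uniform over 0..3
      foot_idx <- which(mask > 0L, arr.ind = TRUE)
      for (k in seq_len(n_spots)) {
        ctr <- foot_idx[sample.int(nrow(foot_idx), 1L), ]
        amp <- stats::runif(1, hot_spot_range[1], hot_spot_range[2])
        sigma <- stats::runif(1, 2, max(3, geometry$width_px / 8))
        row <- matrix(seq_len(geometry$height_px), geometry$height_px, geometry$width_px)
        col <- matrix(seq_len(geometry$width_px), geometry$height_px, geometry$width_px,
                      byrow = TRUE)
        grid <- grid + amp * exp(-((row - ctr[1])^2 + (col - ctr[2])^2) / (2 * sigma^2))
      }
    }
    grid <- pmin(pmax(grid, TEMP_RANGE[1]), TEMP_RANGE[2] - 1e-6)
    list(grid = grid, mask = mask)
  })
  list(id = id, label = label, seed = as.integer(seed),
       left = feet[[1]], right = feet[[2]])
}

#' Generate a synthetic cohort
#'
#' Convenience wrapper drawing `n_healthy` + `n_diabetic` subjects with
#' per-subject seeds derived from `seed`.
#'
#' @param n_healthy,n_diabetic Number of subjects per class.
#' @param geometry A [foot_geometry()].
#' @param seed Root seed.
#' @param ... Passed on to [make_subject()].
#' @return List of subject records.
#' @export
make_cohort <- function(n_healthy, n_diabetic, geometry = foot_geometry(),
                        seed = 1L, ...) {
  labels <- c(rep("healthy", n_healthy), rep("diabetic", n_diabetic))
  lapply(seq_along(labels), function(i) {
    make_subject(labels[i], geometry, seed = seed * 10000L + i,
                 id = sprintf("S%03d", i), ...)
  })
}

#' Generate a tabular two-class benchmark with known informative features
#'
#' Produces a feature table in which a known subset of columns separates
#' the classes by a specified standardized effect size while the remaining
#' columns are pure noise, giving downstream selectors a recoverable
#' ground truth.
#'
#' @param n_per_class Samples per class.
#' @param n_features Total number of feature columns.
#' @param n_informative Number of informative columns (must not exceed
#'   `n_features`).
#' @param effect_size Standardized between-class mean shift (Cohen's d) of
#'   each informative column; non-negative.
#' @param noise_sd Within-class standard deviation (positive).
#' @param seed Integer seed; output is a pure function of it.
#' @return List with `table` (data.frame: `label` factor plus columns
#'   `F001`, `F002`, ...) and `informative` (integer indices of the
#'   informative columns, 1-based among the feature columns).
#' @export
make_tabular <- function(n_per_class = 122L, n_features = 140L,
                         n_informative = 10L, effect_size = 2,
                         noise_sd = 1, seed = 1L) {
  stopifnot(n_per_class >= 1, n_features >= 1, n_informative >= 0,
            effect_size >= 0, noise_sd > 0)
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features")
  }
  set.seed(seed)
  n <- 2L * n_per_class
  x <- matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  informative <- sort(sample.int(n_features, n_informative))
  cls <- rep(c(0, 1), each = n_per_class)
  shift <- effect_size * noise_sd
  x[cls == 1, informative] <- x[cls == 1, informative] + shift
  colnames(x) <- sprintf("F%03d", seq_len(n_features))
  tab <- data.frame(label = factor(ifelse(cls == 1, "diabetic", "healthy"),
                                   levels = c("healthy", "diabetic")),
                    x, check.names = FALSE)
  list(table = tab, informative = informative)
}
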