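#' Construct a 2-D point pattern
#'
#' @param points two-column matrix/data.frame of (x, y) pixel coordinates.
#' @param region bounding rectangle `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the points' bounding box. All points must lie inside and the area must be
#'   positive.
#' @return an object of class `point_pattern`.
#' @export
point_pattern <- function(points, region = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop_validation("points must have two columns (x, y)")
  if (is.null(region)) {
    region <- c(range(pts[, 1]), range(pts[, 2]))
    if (nrow(pts) == 0) region <- c(0, 1, 0, 1)
  }
  area <- (region[2] - region[1]) * (region[4] - region[3])
  if (area <= 0) stop_validation("region must have positive area")
  if (nrow(pts) &&
      (any(pts[, 1] < region[1] - 1e-9) || any(pts[, 1] > region[2] + 1e-9) ||
       any(pts[, 2] < region[3] - 1e-9) || any(pts[, 2] > region[4] + 1e-9)))
    stop_validation("all points must lie inside the region")
  structure(list(points = pts, region = region, area = area, n = nrow(pts)),
            class = "point_pattern")
}

#' Ripley K function of a point pattern
#'
#' `K(d) = (A / n^2) * sum_{i != j} I(d_ij < d)`: the standard estimator, which
#' under complete spatial randomness (CSR) tracks `pi d^2` (exactly so at
#' distances small relative to the region; uncorrected edge effects bias it
#' low as d grows). No edge correction is applied by default (matching how
#' the analysis treats embryo fields); `edge_correction = "translate"` applies
#' the translation correction, which is unbiased under CSR for d below the
#' region's shorter side. An alternative `"intensity"` normalisation
#' `(1/lambda) * sum I / (n lambda) = A^2 sum I / n^3` is available for
#' comparison, where `lambda = n / A`.
#'
#' @param pattern a [point_pattern] with n >= 2.
#' @param d_grid distances (pixels) at which to evaluate K.
#' @param estimator `"standard"` or `"intensity"`.
#' @param edge_correction `"none"` (default) or `"translate"`.
#' @return an object of class `ripley_curve`: data.frame `d`, `K`, with
#'   attributes `n` and `area`.
#' @export
ripley_k <- function(pattern, d_grid, estimator = c("standard", "intensity"),
                     edge_correction = c("none", "translate")) {
  stopifnot(inherits(pattern, "point_pattern"))
  estimator <- match.arg(estimator)
  edge_correction <- match.arg(edge_correction)
  n <- pattern$n
  if (n < 2) stop_validation("Ripley K needs at least 2 points")
  dm <- as.matrix(stats::dist(pattern$points))
  diag(dm) <- Inf
  if (edge_correction == "translate") {
    a <- pattern$region[2] - pattern$region[1]
    b <- pattern$region[4] - pattern$region[3]
    dx <- abs(outer(pattern$points[, 1], pattern$points[, 1], "-"))
    dy <- abs(outer(pattern$points[, 2], pattern$points[, 2], "-"))
    w <- pattern$area / ((a - dx) * (b - dy))  # per-pair translation weight
    diag(w) <- 0
    counts <- vapply(d_grid, function(d) sum(w[dm < d]), numeric(1))
  } else {
    counts <- vapply(d_grid, function(d) sum(dm < d), numeric(1))
  }
  norm <- switch(estimator,
                 standard = pattern$area / n^2,
                 intensity = pattern$area^2 / n^3)
  structure(data.frame(d = d_grid, K = norm * counts),
            class = c("ripley_curve", "data.frame"),
            n = n, area = pattern$area, estimator = estimator,
            edge_correction = edge_correction)
}

#' Compare Ripley K of duplicating centrioles vs all centrioles
#'
#' For each embryo, computes K for the duplication-event positions and for all
#' centriole positions, then averages the curves across embryos. The verdict
#' is "no additional clustering" when each mean curve lies within the other's
#' +/- SD band at every distance.
#'
#' @param div_patterns,all_patterns lists (one per embryo) of
#'   [point_pattern]s: duplicating-centriole positions and all positions.
#' @param d_grid distances, pixels.
#' @return list with `d_grid`, `K_div` / `K_all` (mean curves), `sd_div` /
#'   `sd_all`, `per_embryo` and `overlap` (logical verdict).
#' @export
compare_div_vs_all <- function(div_patterns, all_patterns, d_grid) {
  stopifnot(length(div_patterns) == length(all_patterns))
  kd <- sapply(div_patterns, function(p) ripley_k(p, d_grid)$K)
  ka <- sapply(all_patterns, function(p) ripley_k(p, d_grid)$K)
  kd <- matrix(kd, nrow = length(d_grid)); ka <- matrix(ka, nrow = length(d_grid))
  m_d <- rowMeans(kd); m_a <- rowMeans(ka)
  s_d <- apply(kd, 1, stats::sd); s_a <- apply(ka, 1, stats::sd)
  if (ncol(kd) == 1) { s_d[] <- 0; s_a[] <- 0 }
  overlap <- all(abs(m_d - m_a) <= pmax(s_d, s_a) + 1e-12)
  list(d_grid = d_grid, K_div = m_d, K_all = m_a, sd_div = s_d, sd_all = s_a,
       per_embryo = list(div = kd, all = ka), overlap = overlap)
}

#' Rotate a centriole field onto its principal axes
#'
#' Principal component analysis of the (x, y) positions; coordinates are
#' rotated so the first principal axis (the embryo's long, anterior-posterior
#' axis) maps to y and the second to x. Deterministic sign convention: the
#' first axis points toward larger original y (falling back to larger original
#' x when degenerate), the second toward larger original x.
#'
#' @param points two-column matrix of (x, y) coordinates (>= 3 non-collinear
#'   points).
#' @return list with `rotated` (two-column matrix, x = minor axis, y = major
#'   axis), `rotation` (2x2 matrix applied to centred coordinates), `center`,
#'   and `sdev` (principal standard deviations).
#' @export
pca_align <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3) stop_validation("pca_align needs >= 3 points")
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-12 * max(pc$sdev[1], 1))
    stop_validation("degenerate (collinear) point configuration")
  R <- pc$rotation
  if (R[2, 1] < 0 || (R[2, 1] == 0 && R[1, 1] < 0)) R[, 1] <- -R[, 1]
  if (R[1, 2] < 0) R[, 2] <- -R[, 2]
  centred <- sweep(pts, 2, pc$center)
  scores <- centred %*% R
  rotated <- cbind(x = scores[, 2], y = scores[, 1])
  list(rotated = rotated, rotation = R, center = pc$center, sdev = pc$sdev)
}
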