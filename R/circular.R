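#' Angle samples
#'
#' Two frames of reference are distinguished because the pipeline produces
#' both: `planar_signed` angles live on the full circle \[0, 360) (e.g. 2D
#' projected migration directions relative to the condensate centre) and are
#' valid input for circle-based tests; `axial_magnitude` angles are 3D escape
#' angles in \[0, 180\] (the angle between the net displacement and the
#' start-to-centre axis) whose correct uniformity null is cos(alpha) ~
#' Uniform(-1, 1), tested by [sphere_uniformity_test()].
#'
#' @param angles numeric, degrees.
#' @param frame `"planar_signed"` or `"axial_magnitude"`.
#' @return an `angle_sample`.
#' @export
angle_sample <- function(angles, frame = c("planar_signed", "axial_magnitude")) {
  frame <- match.arg(frame)
  angles <- as.numeric(angles)
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stopf("angle sample is empty")
  if (frame == "planar_signed") {
    angles <- angles %% 360
  } else if (any(angles < 0 | angles > 180)) {
    stopf("axial_magnitude angles must lie in [0, 180]")
  }
  structure(list(angles = angles, frame = frame, n = length(angles)),
            class = "angle_sample")
}

as_angle_sample <- function(x, frame) {
  if (inherits(x, "angle_sample")) x else angle_sample(x, frame)
}

#' Statistical test results
#'
#' Light-weight container for every test the package reports: statistic,
#' p-value, sample sizes, and a `method_note` recording how the p-value was
#' obtained (asymptotic vs permutation/Monte-Carlo, counts, seed).
#'
#' @param statistic_name short statistic label.
#' @param statistic numeric statistic value.
#' @param p_value p-value in \[0,1\].
#' @param n,m sample sizes (m only for two-sample tests).
#' @param method_note free-text provenance note.
#' @param ... extra fields stored on the result.
#' @return a `dc_test_result`.
#' @export
dc_test_result <- function(statistic_name, statistic, p_value, n, m = NA_integer_,
                           method_note = "", ...) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) stopf("p-value outside [0,1]")
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 p_value = p_value, n = n, m = m, method_note = method_note, ...),
            class = "dc_test_result")
}

#' @export
print.dc_test_result <- function(x, ...) {
  cat(sprintf("%s = %.6g, p = %.4g (n = %s%s)\n", x$statistic_name, x$statistic,
              x$p_value, x$n, if (!is.na(x$m)) paste0(", m = ", x$m) else ""))
  if (nzchar(x$method_note)) cat("  ", x$method_note, "\n", sep = "")
  invisible(x)
}

#' Rayleigh Z test of circular uniformity
#'
#' Z = n * Rbar^2 with Rbar the mean resultant length; small p indicates a
#' concentrated (unimodal) direction distribution. The p-value uses the
#' standard series approximation
#' `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2))`,
#' accurate for n >= 10. Requires signed planar angles; axial magnitudes in
#' \[0,180\] have a different null and must go to [sphere_uniformity_test()]
#' (or be converted to signed 2D-projection angles first).
#'
#' @param sample an [angle_sample()] (or numeric degrees) with
#'   `planar_signed` frame.
#' @return a `dc_test_result`.
#' @export
rayleigh_test <- function(sample) {
  sample <- as_angle_sample(sample, "planar_signed")
  if (sample$frame != "planar_signed") {
    stopf(paste("rayleigh_test needs signed planar angles on [0,360);",
                "convert axial magnitudes to signed 2D angles or use",
                "sphere_uniformity_test()"))
  }
  n <- sample$n
  if (n < 4) stopf("rayleigh_test needs n >= 4")
  th <- sample$angles * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(1, max(0, p))
  dc_test_result("Rayleigh Z", z, p, n,
                 method_note = sprintf("asymptotic series p; Rbar = %.4f", rbar),
                 rbar = rbar)
}

# Watson two-sample U2 from group labels in pooled sorted order
watson_u2_from_labels <- function(lab1, n, m) {
  N <- n + m
  d <- cumsum(ifelse(lab1, 1 / n, 0)) - cumsum(ifelse(lab1, 0, 1 / m))
  (n * m / N^2) * (sum(d^2) - sum(d)^2 / N)
}

#' Watson two-sample U-squared test
#'
#' Nonparametric comparison of two circular distributions via the rotation-
#' invariant Cramer-von Mises-type statistic on the pooled circular ranks.
#' The p-value is obtained by label permutation of the pooled sample
#' (add-one smoothed) by default; `exact = TRUE` enumerates all
#' `choose(n+m, n)` assignments (small samples only); classical asymptotic
#' critical values can be consulted via the returned statistic.
#'
#' @param sample1,sample2 [angle_sample()]s (or numeric degrees) in a common
#'   frame of reference.
#' @param n_permutations permutation count (default 9999).
#' @param seed RNG seed recorded in the method note.
#' @param exact enumerate all label assignments instead of sampling.
#' @return a `dc_test_result`.
#' @export
watson_u2_test <- function(sample1, sample2, n_permutations = 9999, seed = 1L,
                           exact = FALSE) {
  s1 <- as_angle_sample(sample1, "planar_signed")
  s2 <- as_angle_sample(sample2, "planar_signed")
  if (s1$frame != s2$frame) stopf("samples use different frames of reference")
  n <- s1$n; m <- s2$n
  if ((n < 8 || m < 8) && !exact) {
    warnf("small samples (n = %d, m = %d < 8): permutation p is coarse; consider exact = TRUE",
          n, m)
  }
  pooled <- c(s1$angles, s2$angles)
  lab <- c(rep(TRUE, n), rep(FALSE, m))
  if (anyDuplicated(pooled)) {
    cross_tie <- any(s1$angles %in% s2$angles)
    if (cross_tie) warnf("ties across the two samples; U2 depends on tie ordering")
  }
  ord <- order(pooled)
  lab_sorted <- lab[ord]
  u2 <- watson_u2_from_labels(lab_sorted, n, m)
  N <- n + m
  if (exact) {
    if (choose(N, n) > 2e5) stopf("exact enumeration infeasible for choose(%d, %d)", N, n)
    combs <- utils::combn(N, n)
    stats_all <- apply(combs, 2, function(ix) {
      l <- rep(FALSE, N); l[ix] <- TRUE
      watson_u2_from_labels(l, n, m)
    })
    p <- mean(stats_all >= u2 - 1e-12)
    note <- sprintf("exact enumeration of %d assignments", ncol(combs))
  } else {
    set.seed(seed)
    perm <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      l <- rep(FALSE, N)
      l[sample.int(N, n)] <- TRUE
      perm[b] <- watson_u2_from_labels(l, n, m)
    }
    p <- (1 + sum(perm >= u2 - 1e-12)) / (n_permutations + 1)
    note <- sprintf("permutation p, %d permutations, seed %d", n_permutations, seed)
  }
  dc_test_result("Watson U2", u2, p, n, m, method_note = note)
}

#' Monte-Carlo test of 3D axial uniformity for escape angles
#'
#' Escape angles are magnitudes in \[0, 180\]; if displacement directions are
#' isotropic in 3D, cos(alpha) is Uniform(-1, 1) regardless of the reference
#' axis. The statistic is the mean of cos(alpha) (positive = net inward
#' motion); p-values come from Monte-Carlo sampling of the null.
#'
#' @param sample an [angle_sample()] (or numeric degrees) with
#'   `axial_magnitude` frame.
#' @param n_mc Monte-Carlo replicates (>= 1000 recommended; fewer warns).
#' @param seed RNG seed.
#' @param alternative `"two.sided"`, `"inward"` (mean cos > 0) or
#'   `"outward"`.
#' @return a `dc_test_result`.
#' @export
sphere_uniformity_test <- function(sample, n_mc = 10000, seed = 1L,
                                   alternative = c("two.sided", "inward", "outward")) {
  alternative <- match.arg(alternative)
  sample <- as_angle_sample(sample, "axial_magnitude")
  if (sample$frame != "axial_magnitude")
    stopf("sphere_uniformity_test expects axial magnitudes in [0,180]")
  if (n_mc < 1000) warnf("n_mc = %d < 1000: p-value resolution is coarse", n_mc)
  n <- sample$n
  stat <- mean(cos(sample$angles * pi / 180))
  set.seed(seed)
  null_stats <- colMeans(matrix(stats::runif(n * n_mc, -1, 1), nrow = n))
  p_hi <- (1 + sum(null_stats >= stat - 1e-12)) / (n_mc + 1)
  p_lo <- (1 + sum(null_stats <= stat + 1e-12)) / (n_mc + 1)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_hi, p_lo)),
              inward = p_hi,
              outward = p_lo)
  dc_test_result("mean cos(alpha)", stat, p, n,
                 method_note = sprintf("Monte-Carlo null (cos ~ U(-1,1)), %d draws, seed %d, alternative %s",
                                       n_mc, seed, alternative))
}
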