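#' Normality-gated two-group (or k-group) location test
#'
#' Implements the testing policy used throughout the package's reports: each
#' group is screened with Shapiro-Wilk at `alpha_normality`; if all groups
#' pass, a two-tailed t-test is used (Welch by default for unpaired designs,
#' paired t when `paired = TRUE`, one-way ANOVA for more than two groups);
#' if any group fails, the nonparametric branch is taken (Mann-Whitney U,
#' Wilcoxon signed-rank when paired, Kruskal-Wallis for more than two
#' groups). Constant-valued groups, for which normality is undefined, fall
#' to the nonparametric branch with a warning. The chosen branch is recorded
#' in `method_note`.
#'
#' @param x numeric values of the first group, or a list of >= 2 groups.
#' @param y numeric values of the second group (ignored when `x` is a list).
#' @param paired paired design (two groups only).
#' @param alpha_normality Shapiro-Wilk screening level.
#' @param welch use Welch's correction for unpaired t-tests.
#' @return a `dc_test_result`.
#' @export
adaptive_location_test <- function(x, y = NULL, paired = FALSE,
                                   alpha_normality = 0.05, welch = TRUE) {
  groups <- if (is.list(x)) x else list(x, y)
  if (any(vapply(groups, is.null, logical(1)))) stopf("two groups are required")
  groups <- lapply(groups, as.numeric)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 3)) stopf("every group needs n >= 3")
  shapiro_p <- vapply(groups, function(g) {
    if (length(unique(g)) == 1L) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (anyNA(shapiro_p)) {
    warnf("constant-valued group: normality undefined, using nonparametric branch")
  }
  normal <- !anyNA(shapiro_p) && all(shapiro_p > alpha_normality)
  k <- length(groups)
  if (k > 2L) {
    if (paired) stopf("paired designs support exactly 2 groups")
    vals <- unlist(groups)
    fac <- factor(rep(seq_len(k), sizes))
    if (normal) {
      fit <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
      return(dc_test_result("one-way ANOVA F", unname(fit$statistic),
                            fit$p.value, sum(sizes),
                            method_note = note_gate("ANOVA", shapiro_p)))
    }
    fit <- stats::kruskal.test(vals, fac)
    return(dc_test_result("Kruskal-Wallis chi-square", unname(fit$statistic),
                          fit$p.value, sum(sizes),
                          method_note = note_gate("Kruskal-Wallis", shapiro_p)))
  }
  x <- groups[[1]]; y <- groups[[2]]
  if (paired && length(x) != length(y)) stopf("paired groups must have equal length")
  if (paired) {
    d <- x - y
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      if (isTRUE(all.equal(mean(d), 0))) {
        return(dc_test_result("paired t", 0, 1, length(x), length(y),
                              method_note = "identical paired samples: no difference"))
      }
      stopf("paired differences are constant and nonzero")
    }
  }
  if (normal) {
    ht <- stats::t.test(x, y, paired = paired, var.equal = !welch && !paired)
    nm <- if (paired) "paired t" else if (welch) "Welch t" else "Student t"
    return(dc_test_result(nm, unname(ht$statistic), ht$p.value,
                          length(x), length(y),
                          method_note = note_gate(nm, shapiro_p)))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired, exact = FALSE,
                                            correct = TRUE))
  nm <- if (paired) "Wilcoxon signed-rank V" else "Mann-Whitney U (W)"
  dc_test_result(nm, unname(ht$statistic), ht$p.value, length(x), length(y),
                 method_note = note_gate(nm, shapiro_p))
}

note_gate <- function(branch, shapiro_p) {
  sprintf("Shapiro-Wilk gate p = [%s] -> %s",
          paste(sprintf("%.3g", shapiro_p), collapse = ", "), branch)
}

#' One-sample t-test of normalized ratios against a null value
#'
#' Used for quantities normalized to a control (fold changes, relative
#' migration), where the control is 1 by construction.
#'
#' @param values numeric ratios (n >= 3).
#' @param null_value null ratio (default 1).
#' @param log_scale test `log(values)` against `log(null_value)`.
#' @return a `dc_test_result`.
#' @export
one_sample_ratio_test <- function(values, null_value = 1, log_scale = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 3) stopf("need n >= 3 values")
  if (log_scale) {
    if (any(values <= 0)) stopf("log scale requires positive values")
    values <- log(values)
    null_value <- log(null_value)
  }
  if (stats::sd(values) == 0) {
    if (all(values == null_value)) {
      return(dc_test_result("one-sample t", 0, 1, length(values),
                            method_note = "all values equal the null value"))
    }
    stopf("zero variance: one-sample t-test undefined")
  }
  ht <- stats::t.test(values, mu = null_value)
  dc_test_result("one-sample t", unname(ht$statistic), ht$p.value, length(values),
                 method_note = sprintf("null value %.4g%s", null_value,
                                       if (log_scale) " (log scale)" else ""))
}

#' Scratch-wound closure
#'
#' Closure at time t is `1 - open_area_t / open_area_t0`, in percent.
#' Accepts a vector of areas for a time series (0, 4, 8, 24 h ...).
#' Wound widening (negative closure) is allowed but warned about.
#'
#' @param open_area_t0 open wound area at time 0 (> 0).
#' @param open_area_t open area(s) at later time point(s) (>= 0).
#' @return closure in percent (vector matching `open_area_t`).
#' @export
wound_closure <- function(open_area_t0, open_area_t) {
  if (open_area_t0 <= 0) stopf("open_area_t0 must be positive")
  if (any(open_area_t < 0)) stopf("open areas must be >= 0")
  closure <- 100 * (1 - open_area_t / open_area_t0)
  if (any(closure < 0)) warnf("negative closure: wound widened at %d time point(s)",
                              sum(closure < 0))
  closure
}

#' Relative transwell migration
#'
#' Ratio of the mean migrated-cell count under a condition to the mean count
#' under the vehicle baseline. Inputs may be replicate vectors (one mean
#' count per experiment) or matrices/data.frames whose rows are replicates
#' and columns the nested counts (duplicate inserts x fields per membrane),
#' which are averaged within replicate first.
#'
#' @param counts_condition,counts_baseline replicate counts (vector) or
#'   nested counts (matrix/data.frame, rows = replicates).
#' @return the migration ratio (baseline = 1).
#' @export
relative_migration <- function(counts_condition, counts_baseline) {
  collapse <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is.matrix(x)) rowMeans(x) else as.numeric(x)
  }
  cond <- collapse(counts_condition)
  base <- collapse(counts_baseline)
  if (!length(cond) || !length(base)) stopf("empty counts")
  if (mean(base) <= 0) stopf("baseline mean must be positive")
  mean(cond) / mean(base)
}

#' Fold change by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt_treated -
#' dCt_control`; `fold = 2^(-ddCt)`. Vector inputs (e.g. triplicate wells)
#' are averaged first. Adding any constant to all four Ct values leaves the
#' fold unchanged.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Ct values (scalars or vectors averaged per group).
#' @return list with `fold`, `ddct`.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- list(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(vapply(cts, function(x) all(is.finite(x)), logical(1)))) {
    stopf("all Ct values must be finite")
  }
  m <- vapply(cts, mean, numeric(1))
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  list(fold = 2^(-ddct), ddct = ddct)
}
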