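#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta quantiles: the lower bound is
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and the upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`); for `x = n` the lower
#' bound reduces to `(alpha/2)^(1/n)`.
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` on the proportion scale.
#' @export
exact_binomial_ci <- function(x, n, level = 0.95) {
  if (n <= 0) stop("n must be > 0")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  alpha <- 1 - level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Agreement rates from a confusion matrix
#'
#' Sensitivity (= PPA when the comparator is an orthogonal method treated as
#' truth) is `100 * tp / (tp + fn)`; specificity (= NPA) is
#' `100 * tn / (tn + fp)`; overall percent agreement is
#' `100 * (tp + tn) / (tp + fp + fn + tn)`. Rates with an empty margin are
#' `NA` (undefined), never 0. Each defined rate carries an exact binomial
#' confidence interval.
#'
#' @param cc a [confusion_counts()].
#' @param level confidence level for the intervals.
#' @return `data.frame` with one row per rate: `rate` name, `percent`,
#'   `ci_low`/`ci_high` (percent scale), `x`, `n`.
#' @export
rates_from_confusion <- function(cc, level = 0.95) {
  stopifnot(inherits(cc, "confusion_counts"))
  tn <- if (is.na(cc$tn)) NA_integer_ else cc$tn
  row <- function(name, x, n) {
    if (is.na(n) || n == 0)
      return(data.frame(rate = name, percent = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, x = NA_integer_, n = n))
    ci <- exact_binomial_ci(x, n, level)
    data.frame(rate = name, percent = 100 * x / n,
               ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
               x = x, n = n)
  }
  total <- cc$tp + cc$fp + cc$fn + ifelse(is.na(tn), 0L, tn)
  out <- rbind(
    row("sensitivity", cc$tp, cc$tp + cc$fn),
    row("specificity", tn, tn + cc$fp),
    row("ppa", cc$tp, cc$tp + cc$fn),
    row("npa", tn, tn + cc$fp),
    row("overall", cc$tp + ifelse(is.na(tn), NA_integer_, tn),
        if (is.na(tn)) NA_integer_ else total)
  )
  rownames(out) <- out$rate
  out
}

#' Limit-of-detection profile across VAF/depth tiers
#'
#' For each tier, Monte-Carlo detection rates under the binomial read-sampling
#' detection model (depth Poisson around the tier target, alternate reads
#' Binomial, detection iff at least `min_alt_reads` alternate reads and the
#' observed VAF clears `reporting_min_vaf`), alongside the analytic
#' expectation `1 - pbinom(min_alt_reads - 1, depth, vaf)` at the nominal
#' depth. Tiers are reported in order of decreasing VAF.
#'
#' @param tiers `data.frame` with columns `vaf`, `depth` and optionally
#'   `truth_n` (variants per tier, default 1).
#' @param min_alt_reads minimum alternate reads for a call.
#' @param reporting_min_vaf caller-level observed-VAF floor.
#' @param n_sims Monte-Carlo draws per tier (>= 1).
#' @param seed seed for the simulation.
#' @return `data.frame` per tier: `vaf`, `depth`, `mc_rate`, `analytic_rate`
#'   (both percents), `n_sims`.
#' @export
lod_profile <- function(tiers, min_alt_reads = 3L, reporting_min_vaf = 0,
                        n_sims = 10000L, seed = 1L) {
  stopifnot(n_sims >= 1, all(c("vaf", "depth") %in% names(tiers)))
  tiers <- tiers[order(-tiers$vaf), , drop = FALSE]
  set.seed(as.integer(seed))
  res <- lapply(seq_len(nrow(tiers)), function(i) {
    v <- tiers$vaf[i]; d <- tiers$depth[i]
    det <- sample_snv_detection(rep(v, n_sims), d, min_alt_reads,
                                reporting_min_vaf)
    data.frame(vaf = v, depth = d,
               mc_rate = 100 * mean(det$called),
               analytic_rate = 100 * (1 - stats::pbinom(min_alt_reads - 1, d, v)),
               n_sims = n_sims)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pearson concordance between paired measurements
#'
#' Product-moment correlation with a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom (via [stats::cor.test()]).
#' p-values below 1e-5 are additionally formatted `"<1e-05"`.
#'
#' @param x,y paired numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `n`, `p_value`, `p_label`.
#' @export
pearson_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("measurements must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- ct$p.value
  list(r = unname(ct$estimate), n = length(x), p_value = p,
       p_label = if (p < 1e-5) "<1e-05" else format(p, digits = 3))
}

#' Quality-control gating policy
#'
#' The assay's sample-level QC gate: input DNA amount >= 50 ng, library
#' amount >= 600 ng, average effective sequencing depth >= 500x in 2%-VAF
#' mode or >= 1000x in 0.5%-VAF mode, fraction of target covered at >= 50x
#' of at least 99%, and fraction of bases at quality >= Q30 of at least 80%.
#' All comparisons are inclusive.
#'
#' @param min_dna_ng,min_library_ng input thresholds (ng).
#' @param min_mean_depth_2pct,min_mean_depth_05pct mode-dependent depth.
#' @param min_fraction_50x,min_fraction_q30 coverage/quality fractions.
#' @return a `qc_policy` list.
#' @export
qc_policy <- function(min_dna_ng = 50, min_library_ng = 600,
                      min_mean_depth_2pct = 500, min_mean_depth_05pct = 1000,
                      min_fraction_50x = 0.99, min_fraction_q30 = 0.80) {
  pol <- list(min_dna_ng = min_dna_ng, min_library_ng = min_library_ng,
              min_mean_depth_2pct = min_mean_depth_2pct,
              min_mean_depth_05pct = min_mean_depth_05pct,
              min_fraction_50x = min_fraction_50x,
              min_fraction_q30 = min_fraction_q30)
  if (any(unlist(pol) <= 0)) stop("all QC thresholds must be positive")
  class(pol) <- "qc_policy"
  pol
}

#' Gate a sample on QC metrics
#'
#' @param metrics named list/vector with `dna_ng`, `library_ng`, `mean_depth`,
#'   `fraction_50x`, `fraction_q30`.
#' @param policy a [qc_policy()].
#' @param mode `"2pct"` (500x floor) or `"0.5pct"` (1000x floor), selecting
#'   the depth requirement for the intended VAF tier.
#' @return list with logical `pass` and character `failures` (empty on pass);
#'   a missing metric fails as `"missing:<name>"`.
#' @export
qc_gate <- function(metrics, policy = qc_policy(), mode = c("2pct", "0.5pct")) {
  mode <- match.arg(mode)
  need <- c("dna_ng", "library_ng", "mean_depth", "fraction_50x", "fraction_q30")
  failures <- character(0)
  for (m in need) {
    if (is.null(metrics[[m]]) || is.na(metrics[[m]]))
      failures <- c(failures, paste0("missing:", m))
  }
  if (length(failures) == 0L) {
    depth_floor <- if (mode == "2pct") policy$min_mean_depth_2pct
                   else policy$min_mean_depth_05pct
    checks <- c(
      dna_ng = metrics$dna_ng >= policy$min_dna_ng,
      library_ng = metrics$library_ng >= policy$min_library_ng,
      mean_depth = metrics$mean_depth >= depth_floor,
      fraction_50x = metrics$fraction_50x >= policy$min_fraction_50x,
      fraction_q30 = metrics$fraction_q30 >= policy$min_fraction_q30
    )
    failures <- names(checks)[!checks]
  }
  list(pass = length(failures) == 0L, failures = failures, mode = mode)
}
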