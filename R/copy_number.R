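#' Mitochondrial base fraction of a run
#'
#' The fraction of sequenced bases attributed to mtDNA,
#' `mt_bases / all_bases`. Under unbiased shotgun sampling this fraction
#' estimates `kM / (2N + kM)`, where k is the mtDNA copy number, M the mtDNA
#' length and 2N the diploid nuclear base count.
#'
#' @param run a `run_count`, or any list with `mt_bases` and `all_bases`.
#' @return numeric fraction in `[0, 1]`.
#' @export
mito_ratio <- function(run) {
  if (is.null(run$all_bases) || run$all_bases <= 0)
    mc_stop("mitocount_degenerate_error",
            "mito_ratio undefined: all_bases must be positive")
  run$mt_bases / run$all_bases
}

#' Estimate the mtDNA copy number
#'
#' Inverts the sampling identity `mtBases/allBases = kM/(2N + kM)`:
#' `k = mtBases * ploidy_factor * N / ((allBases - mtBases) * M)`.
#'
#' @param mt_bases total bases of reads judged mitochondrial.
#' @param all_bases total bases of all reads.
#' @param params a [genome_params()].
#' @return estimated copies k (real, >= 0).
#' @export
estimate_copies <- function(mt_bases, all_bases, params) {
  stopifnot(inherits(params, "genome_params"))
  if (mt_bases < 0 || all_bases <= mt_bases)
    mc_stop("mitocount_degenerate_error",
            "degenerate input: need all_bases > mt_bases >= 0 (got %s, %s)",
            format(all_bases), format(mt_bases))
  (mt_bases * params$ploidy_factor * params$N) / ((all_bases - mt_bases) * params$M)
}

#' Pool runs and estimate the copy number
#'
#' Sums `mt_bases` and `all_bases` across runs, applies [estimate_copies()]
#' to the pooled totals, and retains the per-run mitochondrial ratios (the
#' inputs to [oneway_anova()]).
#'
#' @param runs non-empty list of `run_count` objects.
#' @param params a [genome_params()].
#' @return a `copy_number_estimate` with `k`, `k_rounded` (2 decimals),
#'   `per_run_ratios`, `pooled_mt_bases`, `pooled_all_bases`,
#'   `genome_params`.
#' @export
aggregate_runs <- function(runs, params) {
  if (length(runs) == 0)
    mc_stop("mitocount_input_error", "aggregate_runs requires at least one run")
  mt <- sum(vapply(runs, function(r) as.numeric(r$mt_bases), numeric(1)))
  all <- sum(vapply(runs, function(r) as.numeric(r$all_bases), numeric(1)))
  ratios <- vapply(runs, mito_ratio, numeric(1))
  k <- estimate_copies(mt, all, params)
  structure(list(k = k, k_rounded = round(k, 2), per_run_ratios = ratios,
                 pooled_mt_bases = mt, pooled_all_bases = all,
                 genome_params = params),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("mtDNA copy number estimate: k = %.2f (%d runs, pooled ratio %.4g)\n",
              x$k, length(x$per_run_ratios),
              x$pooled_mt_bases / x$pooled_all_bases))
  invisible(x)
}

#' One-way fixed-effects ANOVA on per-run ratios
#'
#' Classical between/within sum-of-squares decomposition with the p-value
#' from the F distribution. With zero within-group variance and unequal
#' group means the statistic is reported as infinite with p = 0.
#'
#' @param groups list (length >= 2) of numeric vectors, each of length >= 2:
#'   the per-run mitochondrial ratios of each sample.
#' @return an `anova_result` with `F`, `df_between`, `df_within`, `p_value`,
#'   `group_means`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    mc_stop("mitocount_input_error", "oneway_anova requires at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    mc_stop("mitocount_input_error",
            "every group needs at least 2 observations (group %d has %d)",
            which(sizes < 2)[1], min(sizes))
  x <- unlist(groups, use.names = FALSE)
  g <- length(groups)
  n <- length(x)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(x)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- g - 1L
  df_w <- n - g
  if (ss_within == 0) {
    f <- if (ss_between > 0) Inf else 0
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(F = f, df_between = df_b, df_within = df_w,
                 p_value = p, group_means = means),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}
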