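#' Relate RT advance to nascent transcription across conditions
#'
#' Given an ordered series of conditions (e.g. increasing inducer dose or
#' time after induction), each with a domain-level RT advance and a
#' target-gene nascent expression value, computes the Spearman rank
#' correlation between advance and expression, and descriptively detects
#' a plateau: the smallest covariate value beyond which every successive
#' advance changes by less than `plateau_tol` (default 10% of the maximum
#' advance). Spearman is used because dose-response curves that saturate
#' are monotone but not linear.
#'
#' @param series data.frame with one row per condition: `condition`
#'   (label), `covariate` (sortable numeric, e.g. dose or hours), `delta`
#'   (RT advance) and `expression` (target-gene nascent RPKM or rate).
#' @param plateau_tol absolute tolerance on successive delta changes;
#'   default `0.1 * max(delta)`.
#' @return list: `spearman` (NA with a warning when either variable is
#'   constant), `table` (the series sorted by covariate, with ranks),
#'   `plateau_covariate` (NA when no plateau).
#' @export
advance_vs_expression <- function(series, plateau_tol = NULL) {
  series <- as.data.frame(series)
  stopifnot(all(c("condition", "covariate", "delta", "expression") %in%
                  names(series)))
  if (nrow(series) < 3)
    stop("need at least 3 conditions")
  series <- series[order(series$covariate), , drop = FALSE]
  rho <- if (stats::sd(series$delta) == 0 ||
             stats::sd(series$expression) == 0) {
    warning("constant advance or expression across conditions; ",
            "Spearman correlation undefined")
    NA_real_
  } else {
    stats::cor(series$delta, series$expression, method = "spearman")
  }
  if (is.null(plateau_tol)) plateau_tol <- 0.1 * max(abs(series$delta))
  plateau <- NA_real_
  if (nrow(series) >= 2 && plateau_tol > 0) {
    dd <- abs(diff(series$delta))
    flat_from <- which(rev(cumprod(rev(dd < plateau_tol))) == 1)
    if (length(flat_from))
      plateau <- series$covariate[min(flat_from)]
  }
  series$delta_rank <- rank(series$delta)
  series$expression_rank <- rank(series$expression)
  list(spearman = rho, table = series, plateau_covariate = plateau)
}

#' Reversibility report for an induced RT advance
#'
#' Compares three arms — induced, induction-withdrawn, and never-induced
#' baseline — and flags the advance as reversible iff the withdrawn arm's
#' replicate range overlaps the baseline's replicate range and its count
#' of significant windows has returned to at most the baseline's.
#'
#' @param induced,withdrawn,baseline `rt_advance` objects; each may carry
#'   an optional `n_significant` attribute (count of significant windows
#'   from [window_significance()]), otherwise 0 is assumed.
#' @return list: `reversible` (logical), per-arm deltas and ranges.
#' @export
reversibility_report <- function(induced, withdrawn, baseline) {
  for (a in list(induced, withdrawn, baseline))
    if (!inherits(a, "rt_advance"))
      stop("all three arms must be rt_advance objects")
  nsig <- function(a) {
    v <- attr(a, "n_significant")
    if (is.null(v)) 0L else v
  }
  overlap <- withdrawn$replicate_range[1] <= baseline$replicate_range[2] &&
    baseline$replicate_range[1] <= withdrawn$replicate_range[2]
  reversible <- overlap && nsig(withdrawn) <= nsig(baseline)
  list(reversible = reversible,
       induced = list(delta = induced$delta,
                      range = induced$replicate_range,
                      n_significant = nsig(induced)),
       withdrawn = list(delta = withdrawn$delta,
                        range = withdrawn$replicate_range,
                        n_significant = nsig(withdrawn)),
       baseline = list(delta = baseline$delta,
                       range = baseline$replicate_range,
                       n_significant = nsig(baseline)))
}
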