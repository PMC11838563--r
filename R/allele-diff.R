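#' Per-bin allelic RT difference
#'
#' Computes `delta = rt(allele 1) - rt(allele 2)` per bin and replicate.
#' Positive delta means allele 1 replicates earlier. A bin is masked in
#' the delta profile whenever it is masked on either allele. Both inputs
#' must be on the same grid, same replicates, unscaled (the statistics
#' path never sees display scaling).
#'
#' @param rt_a1 an `rt_profile`; either a single-allele profile (then
#'   `rt_a2` is required) or a two-allele profile (then `rt_a2` must be
#'   `NULL` and the difference is first minus second allele in the order
#'   of `alleles`).
#' @param rt_a2 an `rt_profile` for the second allele, or `NULL`.
#' @param alleles length-2 character giving the allele order when
#'   splitting a two-allele profile.
#' @return a `delta_profile` data.frame: `chrom`, `start`, `end`,
#'   `replicate`, `delta`, `masked`; bin size in attribute.
#' @export
allele_delta <- function(rt_a1, rt_a2 = NULL, alleles = c("a1", "a2")) {
  stopifnot(inherits(rt_a1, "rt_profile"))
  stop_if_scaled(rt_a1, "allelic difference")
  if (is.null(rt_a2)) {
    found <- unique(rt_a1$allele)
    if (!all(alleles %in% found))
      stop("profile does not contain both alleles ",
           paste(alleles, collapse = ", "))
    rt_a2 <- rt_a1[rt_a1$allele == alleles[2], , drop = FALSE]
    rt_a2 <- rt_profile(rt_a2, rt_bin_size(rt_a1), rt_state(rt_a1))
    p1 <- rt_a1[rt_a1$allele == alleles[1], , drop = FALSE]
    rt_a1 <- rt_profile(p1, rt_bin_size(rt_a2), rt_state(rt_a2))
  } else {
    stopifnot(inherits(rt_a2, "rt_profile"))
    stop_if_scaled(rt_a2, "allelic difference")
    if (rt_state(rt_a1) != rt_state(rt_a2))
      stop("allele profiles are in different normalization states")
  }
  if (!isTRUE(all.equal(rt_bin_size(rt_a1), rt_bin_size(rt_a2))))
    stop("bin size mismatch between alleles")
  k1 <- paste(rt_a1$chrom, rt_a1$start, rt_a1$replicate)
  k2 <- paste(rt_a2$chrom, rt_a2$start, rt_a2$replicate)
  m <- match(k1, k2)
  if (anyNA(m) || nrow(rt_a1) != nrow(rt_a2))
    stop("allele profiles are not on the same (bin, replicate) grid")
  b <- rt_a2[m, , drop = FALSE]
  masked <- rt_a1$masked | b$masked
  out <- data.frame(chrom = rt_a1$chrom, start = rt_a1$start,
                    end = rt_a1$end, replicate = rt_a1$replicate,
                    delta = ifelse(masked, NA_real_, rt_a1$rt - b$rt),
                    masked = masked, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "bin_size") <- rt_bin_size(rt_a1)
  class(out) <- c("delta_profile", "data.frame")
  out
}

#' Domain-level RT advance, normalized to the wild-type allelic baseline
#'
#' Quantifies how much earlier the modified allele replicates inside a
#' domain, over and above any natural allelic asymmetry present in wild
#' type. The per-bin wild-type baseline is the mean WT delta across WT
#' replicates; per mutant replicate `r` the advance is the mean over
#' unmasked domain bins of `mutant_delta_r(w) - baseline(w)`. The
#' reported `delta` is the mean over replicates. The error bar
#' (`replicate_range`) is the min and max over replicate-pair estimates
#' `A(r, s) = mean_w[mutant_delta_r(w) - wt_delta_s(w)]`, i.e. the range
#' of the domain-level allelic difference across all pairings of a mutant
#' replicate experiment with a wild-type one — the spread actually
#' attributable to replicate experiments.
#'
#' @param mutant_delta `delta_profile` of the engineered sample.
#' @param wt_delta `delta_profile` of wild type, same grid.
#' @param domain single interval: data.frame/list with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return an `rt_advance` object: fields `domain`, `delta`,
#'   `replicate_range` (over replicate pairs), `per_replicate`,
#'   `per_pair`, `n_windows`.
#' @export
rt_advance <- function(mutant_delta, wt_delta, domain) {
  stopifnot(inherits(mutant_delta, "delta_profile"),
            inherits(wt_delta, "delta_profile"))
  domain <- as.data.frame(domain)[1, , drop = FALSE]
  if (!isTRUE(all.equal(attr(mutant_delta, "bin_size"),
                        attr(wt_delta, "bin_size"))))
    stop("mutant and WT delta profiles are on different grids")
  in_dom <- function(d) d$chrom == domain$chrom &
    d$start >= domain$start & d$start < domain$end
  wt_d <- wt_delta[in_dom(wt_delta), , drop = FALSE]
  baseline <- tapply(wt_d$delta, paste(wt_d$chrom, wt_d$start),
                     mean, na.rm = TRUE)
  mut_d <- mutant_delta[in_dom(mutant_delta), , drop = FALSE]
  if (!nrow(mut_d)) stop("no domain bins in the mutant delta profile")
  base_w <- baseline[paste(mut_d$chrom, mut_d$start)]
  adj <- mut_d$delta - base_w
  if (all(is.na(adj))) stop("zero unmasked bins in the domain")
  per_rep <- tapply(adj, mut_d$replicate,
                    function(v) mean(v, na.rm = TRUE))
  # replicate-pair estimates: every mutant replicate experiment against
  # every WT replicate experiment
  mut_reps <- sort(unique(mut_d$replicate))
  wt_reps <- sort(unique(wt_d$replicate))
  key_m <- paste(mut_d$chrom, mut_d$start)
  key_w <- paste(wt_d$chrom, wt_d$start)
  per_pair <- numeric(0)
  for (r in mut_reps) for (s in wt_reps) {
    mr <- mut_d[mut_d$replicate == r, , drop = FALSE]
    ws <- wt_d[wt_d$replicate == s, , drop = FALSE]
    v <- mr$delta - ws$delta[match(paste(mr$chrom, mr$start),
                                   paste(ws$chrom, ws$start))]
    per_pair <- c(per_pair,
                  stats::setNames(mean(v, na.rm = TRUE),
                                  paste0(r, "x", s)))
  }
  n_windows <- length(unique(mut_d$start[!is.na(adj)]))
  structure(list(domain = domain,
                 delta = mean(per_rep, na.rm = TRUE),
                 replicate_range = range(per_pair, na.rm = TRUE),
                 per_replicate = per_rep,
                 per_pair = per_pair,
                 n_windows = n_windows),
            class = "rt_advance")
}

#' @export
print.rt_advance <- function(x, ...) {
  cat(sprintf(
    "RT advance in %s:%s-%s\n  delta = %.4f (log2 E/L units), replicate range [%.4f, %.4f], %d windows\n",
    x$domain$chrom, format(x$domain$start, scientific = FALSE),
    format(x$domain$end, scientific = FALSE),
    x$delta, x$replicate_range[1], x$replicate_range[2], x$n_windows))
  invisible(x)
}

#' Per-window significance of allelic RT changes
#'
#' Tests every 50-kb window for a shift of the mutant allelic delta away
#' from wild type. The effect per window is
#' `mean(mutant delta) - mean(WT delta)` over replicates (reported in the
#' `delta` column); for testing it is standardized into a moderated
#' t-like statistic, dividing by the replicate-based standard error plus
#' a moderation constant (the median standard error across windows, as in
#' SAM-style moderated statistics), which stops low-variance windows from
#' dominating and — crucially — makes windows comparable so their
#' permutation statistics can be pooled. The null is built by randomly
#' permuting replicate group labels and pooling the permuted statistics
#' of windows outside any annotated switching domain into a genome-wide
#' null: with the few replicates typical of Repli-Seq (2-3 per group) the
#' within-window label permutations alone are far too few to resolve
#' small p-values, so the test borrows strength genome-wide; the
#' standardization makes that pooling valid even when noise differs
#' between early- and late-replicating windows. Two-sided p-values are
#' `(1 + #{|null| >= |obs|}) / (1 + N)`, with Benjamini-Hochberg
#' correction across windows; `significant` means `q < fdr`. When either
#' group has a single replicate the raw mean difference is used
#' unstandardized.
#'
#' @param mutant_delta,wt_delta `delta_profile`s on the same grid, with
#'   >= 2 replicates each recommended.
#' @param n_permutations number of label permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param exclude optional data.frame of intervals (`chrom`, `start`,
#'   `end`) — e.g. annotated switching domains — whose windows are kept
#'   out of the genome-wide null pool.
#' @param fdr significance threshold on BH-adjusted q-values.
#' @return data.frame per window: `chrom`, `start`, `end`, `delta`
#'   (observed statistic), `p`, `q`, `significant`.
#' @export
window_significance <- function(mutant_delta, wt_delta,
                                n_permutations = 1000, seed = 1L,
                                exclude = NULL, fdr = 0.05) {
  stopifnot(inherits(mutant_delta, "delta_profile"),
            inherits(wt_delta, "delta_profile"))
  if (n_permutations < 100)
    stop("n_permutations must be >= 100")
  wide <- function(d) {
    reps <- sort(unique(d$replicate))
    key <- paste(d$chrom, d$start)
    bins <- unique(data.frame(chrom = d$chrom, start = d$start,
                              end = d$end, stringsAsFactors = FALSE))
    bk <- paste(bins$chrom, bins$start)
    m <- sapply(reps, function(r) {
      dr <- d[d$replicate == r, , drop = FALSE]
      dr$delta[match(bk, paste(dr$chrom, dr$start))]
    })
    list(bins = bins, mat = matrix(m, nrow = nrow(bins)))
  }
  mw <- wide(mutant_delta); ww <- wide(wt_delta)
  if (!identical(mw$bins, ww$bins))
    stop("mutant and WT delta profiles are not on the same window grid")
  bins <- mw$bins
  X <- cbind(mw$mat, ww$mat)
  nm <- ncol(mw$mat); nw <- ncol(ww$mat)
  obs <- rowMeans(mw$mat, na.rm = TRUE) - rowMeans(ww$mat, na.rm = TRUE)
  tested <- is.finite(obs)

  in_excl <- rep(FALSE, nrow(bins))
  if (!is.null(exclude) && nrow(as.data.frame(exclude))) {
    exclude <- as.data.frame(exclude)
    for (i in seq_len(nrow(exclude)))
      in_excl <- in_excl | (bins$chrom == exclude$chrom[i] &
                              bins$start >= exclude$start[i] &
                              bins$start < exclude$end[i])
  }

  set.seed(seed)
  labels <- c(rep(TRUE, nm), rep(FALSE, nw))
  studentize <- nm >= 2 && nw >= 2
  grp_var <- function(g) {
    n_eff <- rowSums(!is.na(g))
    m <- rowMeans(g, na.rm = TRUE)
    v <- (rowSums(g^2, na.rm = TRUE) - n_eff * m^2) /
      pmax(1, n_eff - 1)
    v[n_eff < 2] <- NA_real_
    list(m = m, v = v, n = n_eff)
  }
  raw_stat <- function(lab) {
    g1 <- grp_var(X[, lab, drop = FALSE])
    g2 <- grp_var(X[, !lab, drop = FALSE])
    d <- g1$m - g2$m
    if (!studentize) return(list(d = d, se = rep(0, length(d))))
    list(d = d, se = sqrt(pmax(0, g1$v / g1$n + g2$v / g2$n)))
  }
  obs_rs <- raw_stat(labels)
  s0 <- if (studentize)
    stats::median(obs_rs$se[tested], na.rm = TRUE) else 1
  if (!is.finite(s0) || s0 == 0) s0 <- 1
  t_of <- function(rs) {
    se <- rs$se
    se[!is.finite(se)] <- s0  # windows with too few unmasked replicates
    rs$d / (se + s0)
  }
  t_obs <- t_of(obs_rs)
  keep <- tested & !in_excl
  if (!any(keep))
    stop("no null windows available outside excluded intervals")
  null_list <- vector("list", n_permutations)
  for (b in seq_len(n_permutations)) {
    s <- t_of(raw_stat(sample(labels)))
    null_list[[b]] <- abs(s[keep])
  }
  null_pool <- unlist(null_list, use.names = FALSE)
  null_pool <- sort(null_pool[is.finite(null_pool)])
  N <- length(null_pool)
  ge <- N - findInterval(abs(t_obs) - 1e-12, null_pool)
  p <- (1 + ge) / (1 + N)
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(bins, delta = obs, p = p, q = q,
             significant = !is.na(q) & q < fdr,
             stringsAsFactors = FALSE)
}

#' Classify replication domains across two cell states
#'
#' Labels each domain by the sign of its mean RT in two reference states
#' (e.g. stem cells and neural precursors): early iff mean RT > 0.
#' Constitutive when the sign agrees between states (CE early in both,
#' CL late in both); developmental when it flips, named by the second
#' state (DE = late-to-early, DL = early-to-late).
#'
#' @param state1,state2 `rt_profile`s of the two reference states
#'   (unscaled; alleles and replicates are pooled per domain).
#' @param domains data.frame of intervals `chrom`, `start`, `end`.
#' @return `domains` with columns `mean_rt_state1`, `mean_rt_state2`,
#'   `class` in `c("CE", "DE", "CL", "DL")`.
#' @export
classify_rt_domains <- function(state1, state2, domains) {
  stopifnot(inherits(state1, "rt_profile"), inherits(state2, "rt_profile"))
  stop_if_scaled(state1, "domain classification")
  stop_if_scaled(state2, "domain classification")
  domains <- as.data.frame(domains)
  dom_mean <- function(p, i) {
    sel <- p$chrom == domains$chrom[i] & p$start >= domains$start[i] &
      p$start < domains$end[i] & !p$masked
    if (!any(sel)) stop("domain ", i, " has no unmasked bins in a state")
    mean(p$rt[sel])
  }
  m1 <- vapply(seq_len(nrow(domains)), function(i) dom_mean(state1, i),
               numeric(1))
  m2 <- vapply(seq_len(nrow(domains)), function(i) dom_mean(state2, i),
               numeric(1))
  e1 <- m1 > 0; e2 <- m2 > 0
  cls <- ifelse(e1 & e2, "CE",
                ifelse(!e1 & !e2, "CL", ifelse(e2, "DE", "DL")))
  cbind(domains, mean_rt_state1 = m1, mean_rt_state2 = m2,
        class = cls, stringsAsFactors = FALSE)
}
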