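#' @title RT profile objects
#' @description An `rt_profile` is a data.frame with one row per
#' (chromosome, bin, allele, replicate): columns `chrom`, `start`, `end`,
#' `allele`, `replicate`, `rt` (log2 early/late scale) and `masked`
#' (logical; `rt` is `NA` when masked). Attributes record the bin size and
#' the normalization state, which moves only forward through
#' `raw -> quantile_normalized -> smoothed -> scaled`. Scaled profiles are
#' for display tracks only; every statistics entry point rejects them.
#' @param df bin-level data.frame as above.
#' @param bin_size bin width in bp.
#' @param state normalization state.
#' @return an `rt_profile`.
#' @export
rt_profile <- function(df, bin_size,
                       state = c("raw", "quantile_normalized",
                                 "smoothed", "scaled")) {
  state <- match.arg(state)
  stopifnot(all(c("chrom", "start", "end", "allele", "replicate",
                  "rt", "masked") %in% names(df)))
  attr(df, "bin_size") <- bin_size
  attr(df, "state") <- state
  class(df) <- c("rt_profile", "data.frame")
  df
}

rt_state <- function(p) attr(p, "state")
rt_bin_size <- function(p) attr(p, "bin_size")

.state_rank <- c(raw = 1, quantile_normalized = 2, smoothed = 3, scaled = 4)

set_state <- function(p, new) {
  if (.state_rank[[new]] < .state_rank[[rt_state(p)]])
    stop("normalization state can only move forward (",
         rt_state(p), " -> ", new, " not allowed)")
  attr(p, "state") <- new
  p
}

stop_if_scaled <- function(p, what) {
  if (rt_state(p) == "scaled")
    stop(what, " must not be computed on scaled profiles; ",
         "scaling is for display tracks only")
  invisible(p)
}

#' @export
print.rt_profile <- function(x, ...) {
  cat("RT profile: ", length(unique(x$chrom)), " chromosome(s), ",
      rt_bin_size(x), "-bp bins, state '", rt_state(x), "'\n", sep = "")
  cat("  alleles:", paste(unique(x$allele), collapse = ", "),
      "| replicates:", paste(unique(x$replicate), collapse = ", "), "\n")
  cat("  bins per track:", sum(x$allele == x$allele[1] &
                                 x$replicate == x$replicate[1]),
      "| masked:", sum(x$masked), "/", nrow(x), "rows\n")
  invisible(x)
}

#' Bin read intervals into fixed-width windows
#'
#' Assigns each read to the bin containing its 5' start (start coordinate
#' for + strand, `end - 1` for - strand; start if no strand column),
#' 0-based half-open. Counts are conserved: the binned total equals the
#' number of reads.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, optional `strand`,
#'   and optional grouping columns `allele`, `fraction`, `replicate`
#'   (defaulted to `"unassigned"`, `"all"`, `1` when absent).
#' @param bin_size bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths; reads whose 5'
#'   start lies outside `[0, length)` are an error.
#' @return a `binned_counts` data.frame (`chrom`, `start`, `end`, `allele`,
#'   `fraction`, `replicate`, `count`) covering every bin of every
#'   chromosome in `chrom_lengths`, zero-filled.
#' @export
bin_reads <- function(reads, bin_size, chrom_lengths) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  stopifnot(all(c("chrom", "start", "end") %in% names(reads)),
            !is.null(names(chrom_lengths)))
  if (!all(reads$chrom %in% names(chrom_lengths)))
    stop("reads on chromosomes absent from chrom_lengths")
  pos5 <- if ("strand" %in% names(reads)) {
    ifelse(reads$strand == "-", reads$end - 1, reads$start)
  } else reads$start
  if (any(pos5 < 0) || any(pos5 >= chrom_lengths[reads$chrom]))
    stop("read 5' start beyond chromosome end")
  allele <- if ("allele" %in% names(reads)) reads$allele else "unassigned"
  fraction <- if ("fraction" %in% names(reads)) reads$fraction else "all"
  replicate <- if ("replicate" %in% names(reads)) reads$replicate else 1L

  bin_start <- floor(pos5 / bin_size) * bin_size
  key <- data.frame(chrom = reads$chrom, start = bin_start,
                    allele = allele, fraction = fraction,
                    replicate = replicate, stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)

  grid <- expand_bin_grid(chrom_lengths, bin_size,
                          unique(key[c("allele", "fraction", "replicate")]))
  m <- match(paste(grid$chrom, grid$start, grid$allele, grid$fraction,
                   grid$replicate),
             paste(agg$chrom, agg$start, agg$allele, agg$fraction,
                   agg$replicate))
  grid$count <- ifelse(is.na(m), 0L, agg$count[m])
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("binned_counts", "data.frame")
  grid
}

expand_bin_grid <- function(chrom_lengths, bin_size, groups) {
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    starts <- seq(0, chrom_lengths[[cn]] - 1, by = bin_size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + bin_size, chrom_lengths[[cn]]),
               stringsAsFactors = FALSE)
  }))
  if (nrow(groups) == 0)
    groups <- data.frame(allele = "unassigned", fraction = "all",
                         replicate = 1L, stringsAsFactors = FALSE)
  out <- merge(bins, groups, by = NULL)
  out[order(out$allele, out$replicate, out$fraction, out$chrom, out$start), ,
      drop = FALSE]
}

#' Compute raw RT (log2 early/late) per bin
#'
#' Normalizes each (allele, replicate, fraction) library to counts per
#' million, then sets `rt = log2((E_cpm + pseudocount) /
#' (L_cpm + pseudocount))` per bin. Bins whose raw early + late coverage is
#' below `min_coverage` are masked.
#'
#' @param counts a `binned_counts` data.frame with `fraction` values
#'   `"early"` and `"late"`.
#' @param pseudocount CPM pseudocount guarding against division by zero.
#' @param min_coverage minimum raw E + L reads per bin per allele;
#'   lower-coverage bins are masked.
#' @param drop_unassigned drop the `"unassigned"` allele track
#'   (default TRUE; phased analysis only uses the two alleles).
#' @return an `rt_profile` in state `"raw"`.
#' @export
compute_rt <- function(counts, pseudocount = 0.1, min_coverage = 10,
                       drop_unassigned = TRUE) {
  stopifnot(inherits(counts, "data.frame"),
            all(c("chrom", "start", "end", "allele", "fraction",
                  "replicate", "count") %in% names(counts)))
  if (!all(c("early", "late") %in% unique(counts$fraction)))
    stop("counts must contain both 'early' and 'late' fractions")
  bin_size <- attr(counts, "bin_size")
  if (is.null(bin_size))
    bin_size <- max(counts$end - counts$start)
  if (drop_unassigned)
    counts <- counts[counts$allele != "unassigned", , drop = FALSE]
  e <- counts[counts$fraction == "early", , drop = FALSE]
  l <- counts[counts$fraction == "late", , drop = FALSE]
  key_e <- paste(e$chrom, e$start, e$allele, e$replicate)
  key_l <- paste(l$chrom, l$start, l$allele, l$replicate)
  m <- match(key_e, key_l)
  if (anyNA(m) || nrow(e) != nrow(l))
    stop("early and late fractions do not cover the same bins")
  l <- l[m, , drop = FALSE]

  lib <- paste(e$allele, e$replicate)
  lib_e <- tapply(e$count, lib, sum)[lib]
  lib_l <- tapply(l$count, lib, sum)[lib]
  cpm_e <- ifelse(lib_e > 0, e$count / lib_e * 1e6, 0)
  cpm_l <- ifelse(lib_l > 0, l$count / lib_l * 1e6, 0)
  rt <- log2((cpm_e + pseudocount) / (cpm_l + pseudocount))
  masked <- (e$count + l$count) < min_coverage
  rt[masked] <- NA_real_
  out <- data.frame(chrom = e$chrom, start = e$start, end = e$end,
                    allele = e$allele, replicate = e$replicate,
                    rt = rt, masked = masked, stringsAsFactors = FALSE)
  out <- out[order(out$allele, out$replicate, out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  rt_profile(out, bin_size, "raw")
}

#' Quantile-normalize an RT profile to a reference
#'
#' Replaces each unmasked value of every (allele, replicate) track by the
#' reference value of equal rank, rank taken genome-wide over the track's
#' unmasked bins. The reference distribution is the pool of all unmasked
#' values of `reference` (all alleles and replicates together — each
#' sample is normalized to the wild-type reference as a whole). When a
#' track has as many unmasked bins as the reference pool, its sorted
#' output equals the sorted reference exactly; otherwise reference
#' quantiles are linearly interpolated. Tied sample values receive the
#' average of the tied reference quantiles. Masked bins stay masked.
#'
#' @param profile an `rt_profile` in state `"raw"`.
#' @param reference an `rt_profile` on the same bin size (typically raw
#'   wild-type), or a numeric vector of reference values.
#' @return the profile in state `"quantile_normalized"`.
#' @export
quantile_normalize <- function(profile, reference) {
  stopifnot(inherits(profile, "rt_profile"))
  if (rt_state(profile) != "raw")
    stop("quantile_normalize expects a raw profile")
  if (inherits(reference, "rt_profile")) {
    if (!isTRUE(all.equal(rt_bin_size(reference), rt_bin_size(profile))))
      stop("profile and reference bin sizes differ")
    ref <- reference$rt[!reference$masked]
  } else ref <- as.numeric(reference[!is.na(reference)])
  if (length(ref) < 2) stop("reference needs at least 2 unmasked bins")
  ref_sorted <- sort(ref)
  nref <- length(ref_sorted)
  track <- paste(profile$allele, profile$replicate)
  for (tr in unique(track)) {
    idx <- which(track == tr & !profile$masked)
    n <- length(idx)
    if (n < 2) stop("track ", tr, " has fewer than 2 unmasked bins")
    r <- rank(profile$rt[idx], ties.method = "average")
    xout <- if (n == nref) r else (r - 0.5) / n * nref + 0.5
    xout <- pmin(nref, pmax(1, xout))
    profile$rt[idx] <- stats::approx(seq_len(nref), ref_sorted,
                                     xout = xout)$y
  }
  set_state(profile, "quantile_normalized")
}

#' Smooth an RT profile with a centered sliding mean
#'
#' Per chromosome and track, each bin's value becomes the mean of all
#' unmasked bins whose midpoints lie within `span_bp / 2` of its own
#' midpoint (a 300-kb span over 5-kb bins averages 61 bins in the
#' interior). Chromosome edges use the truncated window; windows with all
#' bins masked stay masked.
#'
#' @param profile an `rt_profile` (raw or quantile-normalized).
#' @param span_bp smoothing span in bp; must be a positive multiple of the
#'   bin size.
#' @return the profile in state `"smoothed"`.
#' @export
smooth_rt <- function(profile, span_bp = 300000) {
  stopifnot(inherits(profile, "rt_profile"))
  bs <- rt_bin_size(profile)
  if (span_bp < bs) stop("span must be >= bin size")
  if (span_bp %% bs != 0) stop("span must be a multiple of the bin size")
  if (.state_rank[[rt_state(profile)]] > .state_rank[["smoothed"]])
    stop("cannot smooth a scaled profile")
  w <- span_bp / (2 * bs)  # half-window in bins
  track <- paste(profile$allele, profile$replicate, profile$chrom)
  for (tr in unique(track)) {
    idx <- which(track == tr)
    idx <- idx[order(profile$start[idx])]
    v <- profile$rt[idx]
    ok <- !profile$masked[idx]
    n <- length(v)
    cs <- cumsum(c(0, ifelse(ok, v, 0)))
    cn <- cumsum(c(0, as.numeric(ok)))
    lo <- pmax(1, seq_len(n) - w)
    hi <- pmin(n, seq_len(n) + w)
    s <- cs[hi + 1] - cs[lo]
    k <- cn[hi + 1] - cn[lo]
    sm <- ifelse(k > 0, s / k, NA_real_)
    profile$rt[idx] <- sm
    profile$masked[idx] <- k == 0
  }
  set_state(profile, "smoothed")
}

#' Scale an RT profile for display tracks
#'
#' Linearly maps values so that the 99.5th percentile of |rt| over
#' unmasked bins equals `target_halfrange` (default 3, compressing the
#' typical log2 E/L dynamic range of roughly -7..7 to roughly -3..3).
#' Scaled profiles are display-only: every statistics entry point refuses
#' them, so scaling can never leak into significance or advance estimates.
#'
#' @param profile a quantile-normalized (optionally smoothed) `rt_profile`.
#' @param target_halfrange target 99.5th-percentile magnitude.
#' @return the profile in state `"scaled"`.
#' @export
scale_rt <- function(profile, target_halfrange = 3.0) {
  stopifnot(inherits(profile, "rt_profile"))
  if (.state_rank[[rt_state(profile)]] < .state_rank[["quantile_normalized"]])
    stop("scale_rt expects a quantile-normalized profile")
  v <- profile$rt[!profile$masked]
  if (!length(v)) stop("cannot scale an all-masked profile")
  q <- stats::quantile(abs(v), 0.995, names = FALSE, type = 7)
  if (q == 0) stop("degenerate profile: 99.5th percentile of |rt| is 0")
  profile$rt <- profile$rt * (target_halfrange / q)
  set_state(profile, "scaled")
}
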