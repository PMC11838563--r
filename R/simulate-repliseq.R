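#' Simulate allele-tagged E/L Repli-Seq counts
#'
#' Generates binned early/late S-phase fraction read counts per allele and
#' replicate from a latent RT landscape. For every bin the total simulated
#' read count (early + late, both alleles) is Poisson with mean
#' `2 * depth_per_fraction`; of these a `1 - exp(-read_length/spacing)`
#' fraction covers at least one diagnostic SNP and is allele-assignable
#' (split symmetrically between alleles), the rest is emitted under allele
#' `"unassigned"`. Each allele's reads fall into the early fraction with
#' probability `p = plogis(k * true_rt)` — a logistic link between latent
#' timing and early-fraction enrichment — and into the late fraction
#' otherwise; replicates are independent.
#'
#' @param landscape an [rt_landscape()].
#' @param depth_per_fraction expected total reads per bin per fraction
#'   (before allele assignment). The default gives about 30 assignable
#'   reads per fraction per 50-kb bin at the default genome settings.
#' @param n_replicates number of independent replicates.
#' @param bin_size bin width in bp (50 kb for the statistics grid,
#'   5 kb for display tracks).
#' @param k steepness of the logistic link.
#' @param seed integer seed; same seed and configuration reproduce the
#'   counts exactly.
#' @return list with `counts` (a `binned_counts` data.frame: `chrom`,
#'   `start`, `end`, `allele`, `fraction`, `replicate`, `count`) and
#'   `truth` (a `sim_truth` data.frame per bin and allele: latent
#'   `true_rt`, early probability `p_early`, expected assignable reads
#'   `nu`; simulation parameters in attributes).
#' @examples
#' g <- genome_spec(data.frame(name = "chr1", length = 2e6))
#' d <- data.frame(chrom = "chr1", start = 0, end = 2e6, class = "CL")
#' sim <- simulate_repliseq(rt_landscape(g, d), seed = 7)
#' head(sim$counts)
#' @export
simulate_repliseq <- function(landscape,
                              depth_per_fraction = 62,
                              n_replicates = 2,
                              bin_size = 50000,
                              k = 2,
                              seed = 1L) {
  stopifnot(inherits(landscape, "rt_landscape"))
  if (depth_per_fraction <= 0) stop("depth_per_fraction must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (n_replicates < 1) stop("need at least one replicate")
  genome <- landscape$genome
  f_assign <- assignable_fraction(genome)
  bins <- genome_bins(genome, bin_size)
  mid <- (bins$start + bins$end) / 2
  rt1 <- true_rt(landscape, bins$chrom, mid, "a1")
  rt2 <- true_rt(landscape, bins$chrom, mid, "a2")
  p1 <- stats::plogis(k * rt1)
  p2 <- stats::plogis(k * rt2)
  nb <- nrow(bins)

  truth <- data.frame(
    chrom = rep(bins$chrom, 2), start = rep(bins$start, 2),
    end = rep(bins$end, 2),
    allele = rep(c("a1", "a2"), each = nb),
    true_rt = c(rt1, rt2), p_early = c(p1, p2),
    nu = rep(2 * depth_per_fraction * f_assign / 2, 2 * nb),
    stringsAsFactors = FALSE)
  attr(truth, "k") <- k
  attr(truth, "depth_per_fraction") <- depth_per_fraction
  attr(truth, "assignable_fraction") <- f_assign
  attr(truth, "bin_size") <- bin_size
  attr(truth, "seed") <- as.integer(seed)
  class(truth) <- c("sim_truth", "data.frame")

  set.seed(seed)
  res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    n_total <- stats::rpois(nb, 2 * depth_per_fraction)
    n_assign <- stats::rbinom(nb, n_total, f_assign)
    n_a1 <- stats::rbinom(nb, n_assign, 0.5)
    n_a2 <- n_assign - n_a1
    n_un <- n_total - n_assign
    e_a1 <- stats::rbinom(nb, n_a1, p1)
    e_a2 <- stats::rbinom(nb, n_a2, p2)
    e_un <- stats::rbinom(nb, n_un, (p1 + p2) / 2)
    res[[r]] <- data.frame(
      chrom = rep(bins$chrom, 6), start = rep(bins$start, 6),
      end = rep(bins$end, 6),
      allele = rep(c("a1", "a1", "a2", "a2", "unassigned", "unassigned"),
                   each = nb),
      fraction = rep(c("early", "late"), each = nb, times = 3),
      replicate = r,
      count = c(e_a1, n_a1 - e_a1, e_a2, n_a2 - e_a2, e_un, n_un - e_un),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, res)
  attr(counts, "bin_size") <- bin_size
  class(counts) <- c("binned_counts", "data.frame")
  list(counts = counts, truth = truth)
}

#' Bin grid of a genome
#'
#' Tiles every chromosome with fixed-width bins (0-based half-open); the
#' last bin of a chromosome is truncated at the chromosome end.
#'
#' @param genome a [genome_spec()].
#' @param bin_size bin width in bp.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
genome_bins <- function(genome, bin_size) {
  stopifnot(inherits(genome, "genome_spec"), bin_size > 0)
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chromosomes$name[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected log2 early/late ratio at finite depth
#'
#' Numerically propagates an early-fraction probability through the
#' sequencing sampling model: with total assignable bin count
#' `N ~ Poisson(2*nu_fraction)` split `E ~ Binomial(N, p)`, `L = N - E`,
#' returns `E[log2((E + c0) / (L + c0))]` by exact enumeration. `c0` is the
#' pseudocount expressed in raw-count units (a CPM pseudocount times
#' library size / 1e6). Used as the independent closed-form oracle for what
#' the raw RT estimator converges to, including its small-count bias.
#'
#' @param p early-fraction probability (vectorized).
#' @param nu expected assignable reads per fraction for the bin (so the
#'   Poisson total has mean `2 * nu`).
#' @param c0 pseudocount in count units.
#' @return expected log2 ratio, same length as `p`.
#' @export
expected_log2_ratio <- function(p, nu, c0 = 0.001) {
  stopifnot(all(p >= 0 & p <= 1), all(nu > 0))
  nu <- rep_len(nu, length(p))
  vapply(seq_along(p), function(i) {
    lam <- 2 * nu[i]
    nmax <- stats::qpois(1 - 1e-10, lam)
    total <- 0
    for (n in 0:nmax) {
      wn <- stats::dpois(n, lam)
      if (wn < 1e-14) next
      e <- 0:n
      be <- stats::dbinom(e, n, p[i])
      total <- total + wn * sum(be * (log2(e + c0) - log2(n - e + c0)))
    }
    total
  }, numeric(1))
}

#' Expected RT advance by numeric propagation
#'
#' Propagates an engineered latent advance through the logistic link and
#' the finite-depth sampling model to the expected shift of the raw
#' log2(E/L) estimator, averaged over the target-domain bins. This is the
#' analytic expectation against which the pipeline's estimated advance is
#' compared: per bin `E[log2 ratio at sigma(k*(x + offset + delta))] -
#' E[log2 ratio at sigma(k*(x + offset))]`, latents clipped to `[-1, 1]`.
#'
#' @param x_base latent RT of the domain bins before any allelic
#'   perturbation (vector over bins).
#' @param delta engineered advance, latent units.
#' @param offset natural allelic offset, latent units.
#' @param k logistic link steepness.
#' @param nu expected assignable reads per fraction per bin.
#' @param c0 pseudocount in count units.
#' @return scalar expected advance on the log2 E/L scale.
#' @export
expected_rt_advance <- function(x_base, delta, offset = 0.1, k = 2,
                                nu = 30, c0 = 0.001) {
  clip <- function(x) pmin(1, pmax(-1, x))
  p_mut <- stats::plogis(k * clip(x_base + offset + delta))
  p_wt <- stats::plogis(k * clip(x_base + offset))
  mean(expected_log2_ratio(p_mut, nu, c0) -
         expected_log2_ratio(p_wt, nu, c0))
}
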