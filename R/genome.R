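#' Describe a hybrid genome for simulation
#'
#' A `genome_spec` captures the minimal facts the simulator needs about an
#' F1-hybrid genome: chromosome sizes, the mean spacing of diagnostic SNPs
#' that distinguish the two parental alleles, and the sequencing read length.
#' The defaults emulate a 129 x castaneus mouse hybrid, where roughly one
#' SNP occurs every 150 bp, so that a 100-bp read covers at least one
#' diagnostic SNP about half the time.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param snp_spacing_mean mean inter-SNP distance in bp (exponential
#'   spacing model). `Inf` means no SNPs at all.
#' @param read_length sequencing read length in bp.
#' @param seed integer seed owned by this genome; simulators derive their
#'   substreams from it.
#' @return an object of class `genome_spec`.
#' @examples
#' g <- genome_spec(data.frame(name = "chr1", length = 20e6))
#' assignable_fraction(g)  # ~0.49 for 100-bp reads over 150-bp spacing
#' @export
genome_spec <- function(chromosomes,
                        snp_spacing_mean = 150,
                        read_length = 100,
                        seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome names")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (!is.numeric(snp_spacing_mean) || snp_spacing_mean <= 0)
    stop("snp_spacing_mean must be > 0 (use Inf for no SNPs)")
  if (read_length <= 0) stop("read_length must be > 0")
  structure(list(
    chromosomes = data.frame(name = as.character(chromosomes$name),
                             length = as.numeric(chromosomes$length),
                             stringsAsFactors = FALSE),
    snp_spacing_mean = snp_spacing_mean,
    read_length = as.numeric(read_length),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Hybrid genome spec:", nrow(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  cat("  SNP spacing mean:", x$snp_spacing_mean, "bp; read length:",
      x$read_length, "bp; seed:", x$seed, "\n")
  invisible(x)
}

#' Fraction of reads assignable to an allele
#'
#' Probability that a read of the genome's read length covers at least one
#' diagnostic SNP, under exponential (Poisson-process) SNP spacing:
#' `1 - exp(-read_length / spacing_mean)`. Reads covering no SNP cannot be
#' phased and are emitted as `unassigned` by the simulators.
#'
#' @param genome a [genome_spec()].
#' @return scalar in `[0, 1]`.
#' @export
assignable_fraction <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  1 - exp(-genome$read_length / genome$snp_spacing_mean)
}

#' Simulate a diagnostic SNP table
#'
#' Draws SNP positions independently per chromosome with exponential
#' inter-SNP spacing of the genome's stated mean, and assigns each SNP a
#' distinct base for each allele. Positions are sorted, unique, 0-based.
#'
#' @param genome a [genome_spec()].
#' @return data.frame with columns `chrom`, `pos` (0-based), `allele1_base`,
#'   `allele2_base`. Empty when `snp_spacing_mean` is `Inf`.
#' @examples
#' g <- genome_spec(data.frame(name = "chr1", length = 1.5e6))
#' snps <- simulate_snp_table(g)
#' nrow(snps)  # close to 1.5e6 / 150 = 10,000
#' @export
simulate_snp_table <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  empty <- data.frame(chrom = character(), pos = numeric(),
                      allele1_base = character(), allele2_base = character(),
                      stringsAsFactors = FALSE)
  if (!is.finite(genome$snp_spacing_mean)) return(empty)
  set.seed(genome$seed)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    len <- genome$chromosomes$length[i]
    # oversample spacings, then trim to chromosome length
    n_guess <- ceiling(len / genome$snp_spacing_mean * 1.3) + 50
    pos <- cumsum(stats::rexp(n_guess, rate = 1 / genome$snp_spacing_mean))
    while (length(pos) && pos[length(pos)] < len) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(stats::rexp(n_guess, 1 / genome$snp_spacing_mean)))
    }
    pos <- floor(pos[pos < len])
    pos <- unique(pos)
    n <- length(pos)
    b1 <- sample(bases, n, replace = TRUE)
    # second allele differs at every SNP
    shift <- sample(1:3, n, replace = TRUE)
    b2 <- bases[(match(b1, bases) - 1 + shift) %% 4 + 1]
    data.frame(chrom = genome$chromosomes$name[i], pos = pos,
               allele1_base = b1, allele2_base = b2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(empty)))
}

#' Define a ground-truth replication-timing landscape
#'
#' The latent RT landscape assigns every genomic position a value in
#' `[-1, +1]` (+1 = earliest-replicating) per allele. It is built from
#' domain annotations: each domain contributes a control point at its
#' midpoint at the level of its class, and the landscape interpolates
#' linearly between control points (flat beyond the outermost midpoints),
#' giving the piecewise-smooth, domain-structured profiles characteristic
#' of mammalian RT data, with a continuum of intermediate values on the
#' transition slopes.
#'
#' Two allele-asymmetric perturbations are supported, both confined to a
#' designated target domain and applied to allele 1 (the "musculus-like"
#' allele):
#' \itemize{
#'   \item `allelic_offset` — a natural baseline shift (default 0.1 latent
#'     units) making allele 1 replicate slightly earlier even in wild type,
#'     which downstream baseline normalization must remove;
#'   \item `advance_delta` — an engineered RT advance (>= 0) on top of the
#'     offset, the quantity the pipeline estimates.
#' }
#'
#' Domains of class `"switching"` are late in the primary cell state and
#' early in the alternative state (`state = "switched"`), emulating a
#' developmentally regulated domain.
#'
#' @param genome a [genome_spec()].
#' @param domains data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `class` in `c("CE", "CL", "switching")`.
#' @param advance_domain single-row data.frame (`chrom`, `start`, `end`)
#'   naming the domain that carries the offset/advance; defaults to the
#'   first `"switching"` domain, or none.
#' @param advance_delta engineered advance on allele 1 inside
#'   `advance_domain`, latent units, >= 0.
#' @param allelic_offset natural allele-1 baseline shift inside
#'   `advance_domain`, latent units.
#' @param levels named latent levels per class.
#' @param state `"primary"` or `"switched"` (switching domains flip early).
#' @return object of class `rt_landscape`.
#' @export
rt_landscape <- function(genome, domains,
                         advance_domain = NULL,
                         advance_delta = 0,
                         allelic_offset = 0.1,
                         levels = c(CE = 0.8, CL = -0.8, switching = -0.8),
                         state = c("primary", "switched")) {
  stopifnot(inherits(genome, "genome_spec"),
            all(c("chrom", "start", "end", "class") %in% names(domains)))
  state <- match.arg(state)
  if (advance_delta < 0) stop("advance_delta must be >= 0")
  if (!all(domains$class %in% names(levels)))
    stop("unknown domain class")
  if (is.null(advance_domain)) {
    sw <- domains[domains$class == "switching", , drop = FALSE]
    if (nrow(sw)) advance_domain <- sw[1, c("chrom", "start", "end")]
  }
  lv <- levels
  if (state == "switched") lv["switching"] <- abs(lv["CE"])
  structure(list(genome = genome, domains = domains,
                 advance_domain = advance_domain,
                 advance_delta = advance_delta,
                 allelic_offset = allelic_offset,
                 levels = lv, state = state),
            class = "rt_landscape")
}

#' Evaluate the latent RT of a landscape
#'
#' @param landscape an [rt_landscape()].
#' @param chrom chromosome name (recycled against `pos`).
#' @param pos positions in bp.
#' @param allele `"a1"` or `"a2"`.
#' @return latent RT values in `[-1, 1]`.
#' @export
true_rt <- function(landscape, chrom, pos, allele = c("a1", "a2")) {
  stopifnot(inherits(landscape, "rt_landscape"))
  allele <- match.arg(allele)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- numeric(n)
  for (cn in unique(chrom)) {
    idx <- chrom == cn
    d <- landscape$domains[landscape$domains$chrom == cn, , drop = FALSE]
    if (!nrow(d)) { out[idx] <- 0; next }
    d <- d[order(d$start), , drop = FALSE]
    mids <- (d$start + d$end) / 2
    vals <- unname(landscape$levels[d$class])
    if (nrow(d) == 1) {
      out[idx] <- vals
    } else {
      out[idx] <- stats::approx(mids, vals, xout = pos[idx], rule = 2)$y
    }
  }
  ad <- landscape$advance_domain
  if (allele == "a1" && !is.null(ad)) {
    inside <- chrom == ad$chrom[1] & pos >= ad$start[1] & pos < ad$end[1]
    out[inside] <- out[inside] + landscape$allelic_offset +
      landscape$advance_delta
  }
  pmin(1, pmax(-1, out))
}

#' @export
print.rt_landscape <- function(x, ...) {
  cat("RT landscape (", x$state, " state): ", nrow(x$domains),
      " domain(s)\n", sep = "")
  if (!is.null(x$advance_domain))
    cat("  target domain ", x$advance_domain$chrom[1], ":",
        x$advance_domain$start[1], "-", x$advance_domain$end[1],
        "; allele-1 offset ", x$allelic_offset,
        ", engineered advance ", x$advance_delta, "\n", sep = "")
  invisible(x)
}
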