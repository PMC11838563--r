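#' Simulate nascent-RNA (Bru-Seq style) counts
#'
#' Draws per-gene, per-allele nascent read counts as
#' `Poisson(rate * gene_length_kb * library_scale)`, where `rate` is the
#' expected nascent reads per kb at unit library scale — a proxy for
#' transcription rate, which a short metabolic-labeling assay measures
#' directly. An optional read-through mode adds a configurable fraction of
#' a reporter's rate to a downstream interval, emulating transcription
#' running past a reporter's polyA terminator.
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @param rates data.frame with `gene`, `allele`, `rate` (reads/kb, >= 0).
#'   Genes absent from `rates` get rate 0 for that allele.
#' @param library_scale multiplicative sequencing-depth scale.
#' @param n_replicates independent replicates.
#' @param readthrough optional list `(reporter=, downstream=, fraction=)`:
#'   gene names and the fraction of the reporter's rate leaking into the
#'   downstream gene (applied per allele).
#' @param seed integer seed.
#' @return `expression_counts` data.frame: `gene`, `allele`, `replicate`,
#'   `length_bp`, `count`; expected counts in attribute `truth`.
#' @export
simulate_bruseq <- function(genes, rates, library_scale = 1,
                            n_replicates = 2, readthrough = NULL,
                            seed = 1L) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(c("gene", "allele", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) stop("rates must be >= 0")
  if (library_scale <= 0) stop("library_scale must be > 0")
  alleles <- sort(unique(rates$allele))
  if (!length(alleles)) alleles <- c("a1", "a2")
  grid <- expand.grid(gene = genes$gene, allele = alleles,
                      stringsAsFactors = FALSE)
  grid$length_bp <- genes$end[match(grid$gene, genes$gene)] -
    genes$start[match(grid$gene, genes$gene)]
  key <- paste(grid$gene, grid$allele)
  grid$rate <- rates$rate[match(key, paste(rates$gene, rates$allele))]
  grid$rate[is.na(grid$rate)] <- 0
  if (!is.null(readthrough)) {
    stopifnot(all(c("reporter", "downstream", "fraction") %in%
                    names(readthrough)))
    if (readthrough$fraction < 0) stop("readthrough fraction must be >= 0")
    for (al in alleles) {
      rep_rate <- grid$rate[grid$gene == readthrough$reporter &
                              grid$allele == al]
      sel <- grid$gene == readthrough$downstream & grid$allele == al
      if (length(rep_rate) && any(sel))
        grid$rate[sel] <- grid$rate[sel] + readthrough$fraction * rep_rate
    }
  }
  mu <- grid$rate * (grid$length_bp / 1000) * library_scale
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(gene = grid$gene, allele = grid$allele, replicate = r,
               length_bp = grid$length_bp,
               count = stats::rpois(nrow(grid), mu),
               stringsAsFactors = FALSE)
  }))
  attr(out, "truth") <- data.frame(gene = grid$gene, allele = grid$allele,
                                   rate = grid$rate, expected_count = mu,
                                   stringsAsFactors = FALSE)
  class(out) <- c("expression_counts", "data.frame")
  out
}

#' Simulate a barcoded-reporter FASTQ file
#'
#' Writes a standard 4-line-record FASTQ in which a set fraction of reads
#' carries one manifest barcode embedded at a random offset, with barcode
#' identities multinomially distributed proportional to `abundances`.
#' All other sequence (background reads, and the flanks of barcoded reads)
#' is rejection-sampled so that no read contains any manifest barcode other
#' than the one intended — making exact-substring barcode counting
#' oracle-checkable against the returned truth table.
#'
#' @param manifest data.frame with `barcode_id` and `sequence` (16-nt,
#'   A/C/G/T, pairwise distinct).
#' @param abundances non-negative weights, one per manifest row. All zero
#'   means a background-only library.
#' @param n_reads total reads to write.
#' @param path output FASTQ path.
#' @param read_length read length (>= 16).
#' @param barcode_fraction fraction of reads carrying a barcode (ignored
#'   when all abundances are zero).
#' @param seed integer seed.
#' @return invisibly, a list with `path`, `truth` (data.frame
#'   `barcode_id`, `embedded` — the realized embedded-read counts) and
#'   `n_reads`.
#' @export
simulate_barcode_fastq <- function(manifest, abundances, n_reads, path,
                                   read_length = 50,
                                   barcode_fraction = 0.5,
                                   seed = 1L) {
  check_manifest(manifest)
  stopifnot(length(abundances) == nrow(manifest), all(abundances >= 0),
            n_reads >= 0, read_length >= 16)
  set.seed(seed)
  n_bc <- if (sum(abundances) > 0) round(barcode_fraction * n_reads) else 0L
  assign <- if (n_bc > 0) {
    as.integer(stats::rmultinom(1, n_bc, abundances / sum(abundances)))
  } else rep(0L, nrow(manifest))
  which_bc <- rep(seq_len(nrow(manifest)), assign)
  if (length(which_bc)) which_bc <- sample(which_bc)

  reads <- character(n_reads)
  n_bg <- n_reads - n_bc
  if (n_bg > 0)
    reads[seq_len(n_bg)] <- clean_random_reads(n_bg, read_length,
                                               manifest$sequence)
  if (n_bc > 0) {
    for (j in seq_len(n_bc)) {
      bc <- manifest$sequence[which_bc[j]]
      repeat {
        bg <- clean_random_reads(1, read_length, character(0))
        off <- sample.int(read_length - 16 + 1, 1)
        candidate <- paste0(substr(bg, 1, off - 1), bc,
                            substr(bg, off + 16, read_length))
        hits <- vapply(manifest$sequence, grepl, logical(1),
                       x = candidate, fixed = TRUE)
        if (sum(hits) == 1 && hits[which_bc[j]]) break
      }
      reads[n_bg + j] <- candidate
    }
  }
  if (n_reads > 0) reads <- reads[sample.int(n_reads)]
  qual <- strrep("I", read_length)
  lines <- character(4 * n_reads)
  if (n_reads > 0) {
    lines[seq(1, 4 * n_reads, 4)] <- paste0("@read", seq_len(n_reads))
    lines[seq(2, 4 * n_reads, 4)] <- reads
    lines[seq(3, 4 * n_reads, 4)] <- "+"
    lines[seq(4, 4 * n_reads, 4)] <- qual
  }
  writeLines(lines, path)
  invisible(list(path = path,
                 truth = data.frame(barcode_id = manifest$barcode_id,
                                    embedded = assign,
                                    stringsAsFactors = FALSE),
                 n_reads = n_reads))
}

check_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("barcode_id", "sequence") %in% names(manifest)))
  if (any(nchar(manifest$sequence) != 16))
    stop("barcodes must be exactly 16 nt")
  if (any(grepl("[^ACGT]", manifest$sequence)))
    stop("barcodes must be over {A,C,G,T}")
  if (anyDuplicated(manifest$sequence))
    stop("duplicate barcode sequences in manifest")
  invisible(TRUE)
}

# random A/C/G/T reads none of which contains any `forbidden` 16-mer
clean_random_reads <- function(n, len, forbidden) {
  bases <- c("A", "C", "G", "T")
  draw <- function(m) {
    chars <- sample(bases, m * len, replace = TRUE)
    do.call(paste0, split(chars, rep(seq_len(len), each = m)))
  }
  out <- draw(n)
  if (length(forbidden)) {
    repeat {
      bad <- Reduce(`|`, lapply(forbidden, grepl, x = out, fixed = TRUE))
      if (!any(bad)) break
      out[bad] <- draw(sum(bad))
    }
  }
  out
}
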