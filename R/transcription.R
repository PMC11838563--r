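#' Quantify nascent transcription per gene and allele
#'
#' Counts reads whose 5' end falls inside each annotated interval,
#' strand-aware, and fills in RPM and RPKM. Nascent libraries from a
#' directional protocol are typically reverse-stranded (the read strand is
#' opposite the gene strand), the default here. Reads carrying an `allele`
#' label (from diagnostic-SNP overlap) contribute to allele-split rows;
#' all reads regardless of label contribute to the pooled `"all"` rows.
#'
#' Alternatively pass a precomputed `expression_counts` table (e.g. from
#' [simulate_bruseq()]) to fill in RPM/RPKM only.
#'
#' @param reads data.frame of read records (`chrom`, `start`, `end`,
#'   `strand`, optional `allele`), or an `expression_counts` data.frame
#'   (`gene`, `allele`, `replicate`, `length_bp`, `count`).
#' @param annotations BED6-style data.frame: `chrom`, `start`, `end`,
#'   `gene`, `score` (ignored), `strand`. A plain `gene`-named data.frame
#'   with those columns also works.
#' @param library_size total mapped reads of the library (for RPM); must
#'   be > 0. For an `expression_counts` input, a named vector per
#'   replicate or a single number.
#' @param strand_mode `"reverse"` (default), `"forward"`, or
#'   `"unstranded"`.
#' @return `expression_table` data.frame: `gene`, `allele`, `replicate`,
#'   `length_bp`, `count`, `rpm`, `rpkm`.
#' @export
quantify_nascent <- function(reads, annotations, library_size,
                             strand_mode = c("reverse", "forward",
                                             "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (inherits(reads, "expression_counts") ||
      all(c("gene", "count", "length_bp") %in% names(reads))) {
    out <- as.data.frame(reads)
    if (!"replicate" %in% names(out)) out$replicate <- 1L
    ls <- if (length(library_size) > 1) {
      unname(library_size[as.character(out$replicate)])
    } else library_size
    out$rpm <- out$count * 1e6 / ls
    out$rpkm <- out$rpm * 1e3 / out$length_bp
    class(out) <- c("expression_table", "data.frame")
    return(out)
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)),
            all(c("chrom", "start", "end", "gene", "strand") %in%
                  names(annotations)))
  ann <- as.data.frame(annotations)
  pos5 <- ifelse(reads$strand == "-", reads$end - 1, reads$start)
  allele <- if ("allele" %in% names(reads)) {
    a <- as.character(reads$allele); a[is.na(a)] <- "unassigned"; a
  } else rep("unassigned", nrow(reads))

  count_one <- function(i) {
    hit <- reads$chrom == ann$chrom[i] & pos5 >= ann$start[i] &
      pos5 < ann$end[i]
    hit <- hit & switch(strand_mode,
                        reverse = reads$strand != ann$strand[i],
                        forward = reads$strand == ann$strand[i],
                        unstranded = TRUE)
    c(all = sum(hit),
      tapply(rep(1L, sum(hit)), factor(allele[hit],
                                       c("a1", "a2", "unassigned")),
             sum, default = 0L))
  }
  cts <- vapply(seq_len(nrow(ann)), count_one, numeric(4))
  lv <- c("all", "a1", "a2", "unassigned")
  out <- data.frame(
    gene = rep(ann$gene, each = 4),
    allele = rep(lv, times = nrow(ann)),
    replicate = 1L,
    length_bp = rep(ann$end - ann$start, each = 4),
    count = as.vector(cts), stringsAsFactors = FALSE)
  out$rpm <- out$count * 1e6 / library_size
  out$rpkm <- out$rpm * 1e3 / out$length_bp
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Read-through fraction past a reporter's terminator
#'
#' Ratio of the downstream interval's RPKM to the reporter's RPKM, the
#' natural length- and depth-normalized measure of transcription leaking
#' past a polyA termination site. Zero when both are silent; an error
#' when the reporter is silent but the downstream interval is not (the
#' ratio is then meaningless).
#'
#' @param expr an `expression_table`.
#' @param reporter,downstream gene names present in `expr`.
#' @param allele which allele rows to use (default `"all"`).
#' @return scalar read-through fraction.
#' @export
readthrough_fraction <- function(expr, reporter, downstream,
                                 allele = "all") {
  pick <- function(g) {
    v <- expr$rpkm[expr$gene == g & expr$allele == allele]
    if (!length(v)) stop("gene '", g, "' not found for allele ", allele)
    mean(v)
  }
  rp <- pick(reporter); dn <- pick(downstream)
  if (rp == 0) {
    if (dn == 0) return(0)
    stop("reporter RPKM is 0 but downstream is expressed; ",
         "read-through fraction undefined")
  }
  dn / rp
}

#' Simple differential expression between two conditions
#'
#' A deliberately simple, fully transparent differential test for nascent
#' counts: counts are library-size normalized (scaled to the mean library
#' size), log2 fold change is computed on condition means with a
#' pseudocount of 1, and the p-value is a two-sided exact Poisson rate
#' test (binomial form via [stats::poisson.test()]) on the summed counts,
#' with library-size totals as exposure. BH correction across genes.
#' Genes with zero counts in both conditions report log2FC 0 and p 1.
#' This is not a negative-binomial shrinkage estimator; it is the minimal
#' calibrated test for the presence of a rate difference.
#'
#' @param counts_a,counts_b matrices (genes x replicates) of raw counts
#'   with matching rownames, or vectors for single replicates.
#' @return data.frame per gene: `gene`, `log2fc` (a over b), `p`, `q`.
#' @export
differential_expression <- function(counts_a, counts_b) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b))
    stop("gene sets differ between conditions")
  genes <- rownames(counts_a)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts_a)))
  lib_a <- colSums(counts_a); lib_b <- colSums(counts_b)
  lib_all <- c(lib_a, lib_b)
  scale_to <- mean(lib_all[lib_all > 0])
  if (!is.finite(scale_to)) scale_to <- 1
  norm <- function(m, lib) {
    sf <- ifelse(lib > 0, scale_to / lib, 0)
    sweep(m, 2, sf, "*")
  }
  mean_a <- rowMeans(norm(counts_a, lib_a))
  mean_b <- rowMeans(norm(counts_b, lib_b))
  log2fc <- log2((mean_a + 1) / (mean_b + 1))
  sum_a <- rowSums(counts_a); sum_b <- rowSums(counts_b)
  Ta <- sum(lib_a); Tb <- sum(lib_b)
  p <- vapply(seq_along(sum_a), function(i) {
    if (sum_a[i] + sum_b[i] == 0) return(1)
    stats::poisson.test(c(sum_a[i], sum_b[i]), c(Ta, Tb))$p.value
  }, numeric(1))
  zero <- sum_a + sum_b == 0
  log2fc[zero] <- 0
  data.frame(gene = genes, log2fc = log2fc, p = p,
             q = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count exact 16-nt barcodes in a FASTQ file
#'
#' A read increments a barcode's count iff the barcode's exact 16-mer
#' occurs as a substring of the read sequence (forward orientation; set
#' `both_strands = TRUE` to also scan the reverse complement). A read
#' matching two or more distinct barcodes is counted for none and logged
#' as ambiguous.
#'
#' @param fastq path to a FASTQ file (plain text, 4-line records).
#' @param manifest data.frame with `barcode_id`, `sequence` (16-nt,
#'   unique).
#' @param both_strands also match the reverse complement of each barcode.
#' @return list: `counts` (data.frame `barcode_id`, `count`),
#'   `n_reads`, `n_ambiguous`.
#' @export
extract_barcodes <- function(fastq, manifest, both_strands = FALSE) {
  check_manifest(manifest)
  reads <- read_fastq(fastq)$sequence
  pats <- manifest$sequence
  if (both_strands) {
    rc <- vapply(pats, revcomp, character(1))
  }
  nb <- nrow(manifest)
  hit <- matrix(FALSE, length(reads), nb)
  for (j in seq_len(nb)) {
    h <- grepl(pats[j], reads, fixed = TRUE)
    if (both_strands) h <- h | grepl(rc[j], reads, fixed = TRUE)
    hit[, j] <- h
  }
  nhits <- if (length(reads)) rowSums(hit) else integer(0)
  ambiguous <- nhits >= 2
  counts <- if (length(reads)) colSums(hit[nhits == 1, , drop = FALSE])
  else rep(0L, nb)
  list(counts = data.frame(barcode_id = manifest$barcode_id,
                           count = as.integer(counts),
                           stringsAsFactors = FALSE),
       n_reads = length(reads),
       n_ambiguous = sum(ambiguous))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Read a plain-text FASTQ file
#'
#' Strict 4-line-record reader: validates the `@` header, the `+`
#' separator and that quality length equals sequence length, reporting
#' the index of the first malformed record.
#'
#' @param path FASTQ path.
#' @return data.frame: `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4")
  n <- length(lines) / 4
  if (n == 0)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(qual) != nchar(seqs))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1])
  data.frame(id = sub("^@", "", hdr), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Barcode reads per million
#'
#' @param counts data.frame with `barcode_id` and `count`, or a numeric
#'   vector.
#' @param total_reads total sequenced reads of the replicate (> 0).
#' @return same shape as `counts` with an `rpm` column (or RPM vector).
#' @export
barcode_rpm <- function(counts, total_reads) {
  if (total_reads <= 0) stop("total_reads must be > 0")
  if (is.data.frame(counts)) {
    counts$rpm <- counts$count * 1e6 / total_reads
    counts
  } else counts * 1e6 / total_reads
}

#' Per-insertion reporter expression and its genome-wide percentile
#'
#' Divides a multi-copy reporter's RPKM by the number of insertions and
#' ranks the per-insertion value against a distribution of gene RPKMs:
#' the percentile is the percentage of genes with strictly lower RPKM.
#'
#' @param reporter_rpkm total reporter RPKM.
#' @param n_insertions number of insertions in the clone (>= 1).
#' @param gene_rpkm numeric vector of gene RPKMs.
#' @return list: `per_insertion_rpkm`, `percentile` (0-100).
#' @export
per_insertion_expression <- function(reporter_rpkm, n_insertions,
                                     gene_rpkm) {
  if (n_insertions < 1) stop("n_insertions must be >= 1")
  v <- reporter_rpkm / n_insertions
  list(per_insertion_rpkm = v,
       percentile = 100 * mean(gene_rpkm < v))
}
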