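ann6 <- function() {
  data.frame(chrom = "chr1", start = c(1000, 10000), end = c(2000, 15000),
             gene = c("gA", "gB"), score = 0, strand = c("+", "-"),
             stringsAsFactors = FALSE)
}

test_that("nascent quantification has the closed-form RPM/RPKM", {
  # 10 reads in a 1-kb gene, library 1e6 -> RPM 10, RPKM 10
  reads <- data.frame(chrom = "chr1", start = seq(1000, 1900, 100),
                      end = seq(1100, 2000, 100), strand = "-")
  e <- quantify_nascent(reads, ann6(), library_size = 1e6)
  row <- e[e$gene == "gA" & e$allele == "all", ]
  expect_equal(row$count, 10)
  expect_equal(row$rpm, 10)
  expect_equal(row$rpkm, 10)
  # empty reads -> all zeros
  e0 <- quantify_nascent(reads[0, ], ann6(), library_size = 1e6)
  expect_true(all(e0$count == 0))
})

test_that("strand mode controls which reads count", {
  # plus-strand read on a plus-strand gene: reverse library counts it
  # only when strands are opposite
  r <- data.frame(chrom = "chr1", start = 1500, end = 1600, strand = "+")
  e_rev <- quantify_nascent(r, ann6(), 1e6, strand_mode = "reverse")
  expect_equal(e_rev$count[e_rev$gene == "gA" & e_rev$allele == "all"], 0)
  e_fwd <- quantify_nascent(r, ann6(), 1e6, strand_mode = "forward")
  expect_equal(e_fwd$count[e_fwd$gene == "gA" & e_fwd$allele == "all"], 1)
  e_un <- quantify_nascent(r, ann6(), 1e6, strand_mode = "unstranded")
  expect_equal(e_un$count[e_un$gene == "gA" & e_un$allele == "all"], 1)
})

test_that("interval-join quantification equals a per-read loop", {
  set.seed(11)
  n <- 1e4
  reads <- data.frame(chrom = "chr1",
                      start = sample(0:20000, n, TRUE),
                      strand = sample(c("+", "-"), n, TRUE),
                      allele = sample(c("a1", "a2", NA), n, TRUE))
  reads$end <- reads$start + 100
  ann <- ann6()
  e <- quantify_nascent(reads, ann, 1e6, strand_mode = "reverse")
  for (gi in seq_len(nrow(ann))) {
    hits <- 0L; hits_a1 <- 0L
    for (i in seq_len(n)) {
      p5 <- if (reads$strand[i] == "-") reads$end[i] - 1 else reads$start[i]
      if (reads$chrom[i] == ann$chrom[gi] && p5 >= ann$start[gi] &&
          p5 < ann$end[gi] && reads$strand[i] != ann$strand[gi]) {
        hits <- hits + 1L
        if (!is.na(reads$allele[i]) && reads$allele[i] == "a1")
          hits_a1 <- hits_a1 + 1L
      }
    }
    expect_equal(e$count[e$gene == ann$gene[gi] & e$allele == "all"], hits)
    expect_equal(e$count[e$gene == ann$gene[gi] & e$allele == "a1"],
                 hits_a1)
  }
})

test_that("read-through fraction handles silent reporters", {
  et <- data.frame(gene = c("rep", "down"), allele = "all", replicate = 1,
                   length_bp = c(2000, 8000), count = c(0, 0),
                   rpm = c(0, 0), rpkm = c(0, 0))
  class(et) <- c("expression_table", "data.frame")
  expect_equal(readthrough_fraction(et, "rep", "down"), 0)
  et$rpkm <- c(0, 5)
  expect_error(readthrough_fraction(et, "rep", "down"), "undefined")
  et$rpkm <- c(100, 5)
  expect_equal(readthrough_fraction(et, "rep", "down"), 0.05)
})

test_that("simulated read-through is recovered at depth", {
  genes <- data.frame(gene = c("HTK", "Down"), chrom = "chr1",
                      start = c(0, 2000), end = c(2000, 10000),
                      strand = "+")
  b <- simulate_bruseq(genes,
                       data.frame(gene = "HTK", allele = "a1", rate = 500),
                       library_scale = 100, n_replicates = 2,
                       readthrough = list(reporter = "HTK",
                                          downstream = "Down",
                                          fraction = 0.05),
                       seed = 13)
  e <- quantify_nascent(b, library_size = 1e6)
  est <- readthrough_fraction(e, "HTK", "Down", allele = "a1")
  # Poisson 3 sigma at ~1e5 reporter reads
  expect_lt(abs(est - 0.05), 3 * 0.05 / sqrt(0.05 * 500 * 2 * 100))
})

test_that("differential expression is calibrated and detects induction", {
  set.seed(14)
  # identical tables -> log2FC 0 everywhere; (0,0) genes -> p 1
  m <- matrix(rpois(40, 50), 20)
  de0 <- differential_expression(m, m)
  expect_true(all(de0$log2fc == 0))
  z <- differential_expression(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(z$p == 1) && all(z$log2fc == 0))
  # null calibration: equal Poisson rates, 2000 genes
  a <- matrix(rpois(4000, 100), 2000)
  b <- matrix(rpois(4000, 100), 2000)
  den <- differential_expression(a, b)
  expect_gte(mean(den$p < 0.05), 0.03 - 0.015)
  expect_lte(mean(den$p < 0.05), 0.07 + 0.015)
  # 4-fold induction of 100 genes over a large unchanged background
  bg_a <- matrix(rpois(2000 * 2, 100), 2000)
  bg_b <- matrix(rpois(2000 * 2, 100), 2000)
  ind_a <- matrix(rpois(100 * 2, 400), 100)
  ind_b <- matrix(rpois(100 * 2, 100), 100)
  de <- differential_expression(rbind(bg_a, ind_a), rbind(bg_b, ind_b))
  med <- stats::median(de$log2fc[2001:2100])
  expect_gte(med, 1.8)
  expect_lte(med, 2.2)
  expect_true(all(de$q[2001:2100] < 0.05))
})

test_that("barcode counting matches the generator truth exactly", {
  man <- test_manifest(4)
  f <- withr::local_tempfile(fileext = ".fastq")
  sim <- simulate_barcode_fastq(man, c(5, 3, 1, 1), 3000, f, seed = 15)
  x <- extract_barcodes(f, man)
  expect_identical(x$counts$count, sim$truth$embedded)
  expect_identical(x$n_ambiguous, 0L)
  expect_identical(x$n_reads, 3000L)
})

test_that("ambiguous and malformed records are handled as specified", {
  man <- data.frame(barcode_id = c("b1", "b2"),
                    sequence = c(strrep("A", 16), strrep("C", 16)))
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", paste0(strrep("A", 16), "GG", strrep("C", 16)),
               "+", strrep("I", 34),
               "@r2", paste0("GG", strrep("A", 16), "GG"),
               "+", strrep("I", 20)), f)
  x <- extract_barcodes(f, man)
  expect_identical(x$counts$count, c(1L, 0L))  # r1 ambiguous, r2 counts b1
  expect_identical(x$n_ambiguous, 1L)
  # empty FASTQ
  fe <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fe)
  xe <- extract_barcodes(fe, man)
  expect_true(all(xe$counts$count == 0L))
  # malformed record reports its index
  fb <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "r2-missing-at", "ACGT", "+", "IIII"), fb)
  expect_error(extract_barcodes(fb, man), "index 2")
})

test_that("reverse-complement scanning is optional", {
  man <- data.frame(barcode_id = "b1", sequence = "AAAAAAAACCCCCCCC")
  f <- withr::local_tempfile(fileext = ".fastq")
  # read contains only the reverse complement of the barcode
  rcseq <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(man$sequence, "")[[1]]),
                        collapse = ""))
  writeLines(c("@r1", paste0("GG", rcseq, "GG"), "+", strrep("I", 20)), f)
  expect_identical(extract_barcodes(f, man)$counts$count, 0L)
  expect_identical(extract_barcodes(f, man,
                                    both_strands = TRUE)$counts$count, 1L)
})

test_that("barcode RPM and per-insertion expression are homogeneous", {
  cts <- data.frame(barcode_id = c("b1", "b2"), count = c(5, 0))
  r <- barcode_rpm(cts, 1e6)
  expect_equal(r$rpm, c(5, 0))
  expect_equal(barcode_rpm(cts, 2e6)$rpm, r$rpm / 2, tolerance = 1e-9)
  expect_error(barcode_rpm(cts, 0), "total_reads")

  pie <- per_insertion_expression(107, 107, c(0.5, 0.9, 2))
  expect_equal(pie$per_insertion_rpkm, 1)
  expect_equal(per_insertion_expression(50, 1, c(1, 2, 3))$percentile, 100)
  expect_error(per_insertion_expression(10, 0, 1:3), "n_insertions")
  # planted reporter at the 99th percentile of a simulated distribution
  set.seed(16)
  genes <- exp(rnorm(5000))
  planted <- stats::quantile(genes, 0.99, names = FALSE) * 1.000001
  pct <- per_insertion_expression(planted * 3, 3, genes)$percentile
  expect_gte(pct, 98)
  expect_lte(pct, 100)
})
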