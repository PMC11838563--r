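test_that("reads are binned by 5' start with conserved totals", {
  cl <- c(chr1 = 1e6)
  # boundary: 5' start 49,999 falls in [0, 50000)
  r <- data.frame(chrom = "chr1", start = 49999, end = 50099)
  b <- bin_reads(r, 50000, cl)
  expect_identical(b$count[b$start == 0], 1L)
  expect_identical(sum(b$count), 1L)
  # minus-strand read binned by its 5' end (end - 1)
  r2 <- data.frame(chrom = "chr1", start = 49000, end = 50001,
                   strand = "-")
  b2 <- bin_reads(r2, 50000, cl)
  expect_identical(b2$count[b2$start == 50000], 1L)
  # conservation on 1000 random reads
  set.seed(1)
  rr <- data.frame(chrom = "chr1",
                   start = sample(0:(1e6 - 200), 1000, TRUE))
  rr$end <- rr$start + 100
  expect_identical(sum(bin_reads(rr, 50000, cl)$count), 1000L)
  # beyond chromosome end
  expect_error(bin_reads(data.frame(chrom = "chr1", start = 1e6,
                                    end = 1e6 + 100), 50000, cl),
               "beyond")
})

test_that("vectorized binning equals a brute-force per-read loop", {
  set.seed(2)
  cl <- c(chr1 = 5e5, chr2 = 3e5)
  n <- 1e4
  reads <- data.frame(
    chrom = sample(names(cl), n, TRUE),
    strand = sample(c("+", "-"), n, TRUE))
  reads$start <- floor(runif(n, 0, cl[reads$chrom] - 150))
  reads$end <- reads$start + 100
  b <- bin_reads(reads, 5e4, cl)
  # brute force: loop every read, increment its bin
  brute <- new.env()
  for (i in seq_len(n)) {
    p5 <- if (reads$strand[i] == "-") reads$end[i] - 1 else reads$start[i]
    key <- paste(reads$chrom[i], floor(p5 / 5e4) * 5e4)
    brute[[key]] <- (brute[[key]] %||% 0L) + 1L
  }
  for (j in seq_len(nrow(b))) {
    key <- paste(b$chrom[j], b$start[j])
    expect_identical(b$count[j], as.integer(brute[[key]] %||% 0L))
  }
})

test_that("log2 E/L has the closed form, symmetry and masking", {
  mk <- function(e, l) {
    n <- length(e)
    data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 5e4,
               end = seq_len(n) * 5e4,
               allele = "a1", fraction = rep(c("early", "late"), each = n),
               replicate = 1L, count = c(e, l), stringsAsFactors = FALSE)
  }
  # E = L > 0 -> rt = 0 (CPM equal, identical libraries)
  p <- compute_rt(mk(c(50, 50), c(50, 50)), pseudocount = 0.1,
                  min_coverage = 10)
  expect_equal(p$rt, c(0, 0))
  # E_cpm = 4c, L_cpm = c, pseudocount << c -> rt ~ 2 (equal library
  # sizes so CPM scaling is neutral)
  p2 <- compute_rt(mk(c(400, 100, 500), c(100, 400, 500)),
                   pseudocount = 1e-6, min_coverage = 1)
  expect_equal(p2$rt, c(2, -2, 0), tolerance = 1e-6)
  # antisymmetry: swapping fraction labels negates rt exactly
  cnt <- mk(c(120, 30, 77), c(20, 90, 61))
  swapped <- cnt
  swapped$fraction <- ifelse(cnt$fraction == "early", "late", "early")
  expect_equal(compute_rt(cnt)$rt, -compute_rt(swapped)$rt)
  # coverage below threshold is masked
  p3 <- compute_rt(mk(c(3, 100), c(4, 100)), min_coverage = 10)
  expect_true(p3$masked[1] && is.na(p3$rt[1]) && !p3$masked[2])
  # missing fraction errors
  one <- mk(c(10, 10), c(10, 10))
  expect_error(compute_rt(one[one$fraction == "early", ]), "late")
})

test_that("quantile normalization maps ranks onto the reference", {
  set.seed(3)
  ref_vals <- sort(rnorm(200))
  ref <- toy_profile(sample(ref_vals))
  # sample already equal to reference -> unchanged
  s0 <- quantile_normalize(ref, ref)
  expect_equal(s0$rt, ref$rt)
  # constant shift is removed exactly (rank invariance)
  sh <- toy_profile(ref$rt + 1.23)
  expect_equal(quantile_normalize(sh, ref)$rt, ref$rt)
  # arbitrary sample: sorted output equals sorted reference (oracle:
  # explicit sort-and-map)
  x <- toy_profile(rcauchy(200))
  qn <- quantile_normalize(x, ref)
  expect_equal(sort(qn$rt), ref_vals)
  oracle <- ref_vals[rank(x$rt)]  # no ties: direct sort-and-map
  expect_equal(qn$rt, oracle)
  # tied sample values get the average of tied reference quantiles
  tie <- toy_profile(c(5, 5, 9))
  r3 <- toy_profile(c(10, 20, 30))
  expect_equal(quantile_normalize(tie, r3)$rt, c(15, 15, 30))
})

test_that("quantile normalization respects masks and degenerate input", {
  set.seed(4)
  ref <- toy_profile(rnorm(50))
  x <- toy_profile(rnorm(50), masked = c(TRUE, rep(FALSE, 49)))
  qn <- quantile_normalize(x, ref)
  expect_true(qn$masked[1] && is.na(qn$rt[1]))
  expect_equal(sum(qn$masked), 1L)
  tiny <- toy_profile(c(1, NA), masked = c(FALSE, TRUE))
  expect_error(quantile_normalize(tiny, ref), "fewer than 2")
  expect_error(quantile_normalize(toy_profile(rnorm(10)),
                                  toy_profile(0, masked = TRUE)),
               "at least 2")
})

test_that("sliding-mean smoothing matches a brute-force window mean", {
  n <- 200
  const <- toy_profile(rep(0.7, n), bin_size = 5000)
  expect_equal(smooth_rt(const, 300000)$rt, rep(0.7, n))
  # linear ramp: symmetric interior windows leave values unchanged
  ramp <- toy_profile(seq(0, 1, length.out = n), bin_size = 5000)
  sm <- smooth_rt(ramp, 300000)
  w <- 30
  interior <- (w + 1):(n - w)
  expect_equal(sm$rt[interior], ramp$rt[interior], tolerance = 1e-12)
  # single spike: exact brute-force window means, peak <= h / 60
  h <- 6
  spike <- c(rep(0, 99), h, rep(0, 100))
  sp <- smooth_rt(toy_profile(spike, bin_size = 5000), 300000)
  brute <- vapply(seq_len(n), function(i) {
    j <- max(1, i - w):min(n, i + w)
    mean(spike[j])
  }, numeric(1))
  expect_equal(sp$rt, brute, tolerance = 1e-12)
  expect_lte(max(sp$rt), h / 60)
  # masked bins are omitted; all-masked windows stay masked
  m <- rep(FALSE, n); m[1:80] <- TRUE
  pm <- smooth_rt(toy_profile(spike, masked = m, bin_size = 5000), 3e5)
  expect_true(all(pm$masked[1:(80 - w - 1)]))
  expect_false(any(pm$masked[(80 + 1):n]))
  expect_error(smooth_rt(toy_profile(spike, bin_size = 5000), 2500),
               "span")
})

test_that("display scaling hits the percentile target and is idempotent", {
  set.seed(5)
  v <- rnorm(1000, sd = 3)
  v <- v / stats::quantile(abs(v), 0.995) * 7  # 99.5th pct of |v| = 7
  p <- toy_profile(v, state = "quantile_normalized")
  sc <- scale_rt(p, 3)
  expect_equal(stats::quantile(abs(sc$rt), 0.995, names = FALSE), 3,
               tolerance = 1e-9)
  # scaling twice changes nothing further
  sc2 <- scale_rt(rt_profile(as.data.frame(sc), 50000,
                             "quantile_normalized"), 3)
  expect_equal(sc2$rt, sc$rt, tolerance = 1e-9)
  allm <- toy_profile(rep(1, 5), masked = rep(TRUE, 5),
                      state = "quantile_normalized")
  expect_error(scale_rt(allm), "all-masked")
  zero <- toy_profile(c(0, 0, NA), masked = c(FALSE, FALSE, TRUE),
                      state = "quantile_normalized")
  expect_error(scale_rt(zero), "degenerate")
})

test_that("normalization state only moves forward; scaling never feeds stats", {
  set.seed(6)
  ref <- toy_profile(rnorm(100))
  p <- quantile_normalize(toy_profile(rnorm(100)), ref)
  expect_identical(attr(p, "state"), "quantile_normalized")
  expect_error(quantile_normalize(p, ref), "raw")
  sc <- scale_rt(p)
  expect_error(smooth_rt(sc, 300000), "scaled")
  expect_error(allele_delta(sc, sc), "display")
  expect_error(scale_rt(toy_profile(rnorm(100))), "quantile-normalized")
})

test_that("raw RT recovers the latent landscape ordering", {
  land <- rt_landscape(test_genome(), test_domains())
  s <- simulate_repliseq(land, 62, 2, 50000, seed = 5)
  p <- compute_rt(s$counts)
  m <- merge(as.data.frame(p)[p$replicate == 1 & !p$masked, ],
             s$truth, by = c("chrom", "start", "allele"))
  expect_gte(stats::cor(m$rt, m$true_rt, method = "spearman"), 0.9)
})
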