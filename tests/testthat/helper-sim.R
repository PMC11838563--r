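`%||%` <- function(a, b) if (is.null(a)) b else a

# shared fixtures: a 20-Mb hybrid chromosome with mixed domain structure
# and a 2-Mb switching (late) domain whose allele 1 can be advanced

test_genome <- function(length = 20e6, seed = 1L) {
  genome_spec(data.frame(name = "chr1", length = length), seed = seed)
}

test_domains <- function() {
  data.frame(chrom = "chr1",
             start = c(0, 4e6, 8e6, 9e6, 11e6, 15e6),
             end   = c(4e6, 8e6, 9e6, 11e6, 15e6, 20e6),
             class = c("CE", "CL", "CE", "switching", "CL", "CE"),
             stringsAsFactors = FALSE)
}

test_target_domain <- function() {
  data.frame(chrom = "chr1", start = 9e6, end = 11e6)
}

# simulate one arm and return its quantile-normalized delta profile,
# plus the WT reference pieces when wt = TRUE
sim_delta <- function(advance_delta, wt_raw, seed,
                      n_replicates = 3, depth = 62) {
  land <- rt_landscape(test_genome(), test_domains(),
                       advance_delta = advance_delta)
  s <- simulate_repliseq(land, depth, n_replicates, 50000, seed = seed)
  allele_delta(quantile_normalize(compute_rt(s$counts), wt_raw))
}

# a small manually-built rt_profile: one allele, one replicate
toy_profile <- function(rt, masked = rep(FALSE, length(rt)),
                        bin_size = 50000, allele = "a1", replicate = 1L,
                        state = "raw") {
  n <- length(rt)
  rt[masked] <- NA_real_
  rt_profile(data.frame(chrom = "chr1",
                        start = (seq_len(n) - 1) * bin_size,
                        end = seq_len(n) * bin_size,
                        allele = allele, replicate = replicate,
                        rt = rt, masked = masked,
                        stringsAsFactors = FALSE),
             bin_size, state)
}

# manually-built delta profile over n windows x replicates (matrix cols)
toy_delta <- function(delta_mat, bin_size = 50000) {
  n <- nrow(delta_mat)
  out <- do.call(rbind, lapply(seq_len(ncol(delta_mat)), function(r)
    data.frame(chrom = "chr1", start = (seq_len(n) - 1) * bin_size,
               end = seq_len(n) * bin_size, replicate = r,
               delta = delta_mat[, r], masked = is.na(delta_mat[, r]),
               stringsAsFactors = FALSE)))
  attr(out, "bin_size") <- bin_size
  class(out) <- c("delta_profile", "data.frame")
  out
}

test_manifest <- function(n = 3, seed = 1) {
  set.seed(seed)
  draw <- function() paste(sample(c("A", "C", "G", "T"), 16, TRUE),
                           collapse = "")
  seqs <- character(0)
  while (length(seqs) < n) seqs <- unique(c(seqs, draw()))
  data.frame(barcode_id = paste0("bc", seq_len(n)), sequence = seqs[1:n],
             stringsAsFactors = FALSE)
}
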