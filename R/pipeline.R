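#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> RT -> quantile-normalize -> (display: smooth +
#' scale tracks) -> allelic delta -> domain advance + per-window
#' significance -> nascent transcription quantification -> advance-vs-
#' expression association, and writes all artifacts plus a checksum
#' manifest into `outdir`. All randomness flows from the root `seed` via
#' named per-stage substreams, so a rerun with the same configuration and
#' seed reproduces every output byte for byte.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   `outdir`, `seed`, `genome` (`chromosomes` list of `name`/`length`,
#'   `snp_spacing_mean`, `read_length`), `domains` (list of
#'   `chrom`/`start`/`end`/`class`), `advance_domain`, `allelic_offset`,
#'   `repliseq` (`depth_per_fraction`, `n_replicates`, `bin_size`, `k`,
#'   `n_permutations`), `display` (`bin_size`, `span_bp`,
#'   `target_halfrange`, `enabled`), `genes` (list of
#'   `gene`/`chrom`/`start`/`end`/`strand`), `target_gene`, `bruseq`
#'   (`library_scale`, `n_replicates`, `library_size` — total mapped
#'   reads per replicate used for RPM), and `conditions` (list of
#'   `label`/`covariate`/`advance_delta`/`target_rate`).
#' @return invisibly, a list with the per-condition advances, the
#'   association result, the expression table, and `manifest` (path).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$outdir, paste0(...))
  files <- character(0)

  genome <- genome_spec(cfg$genome$chromosomes,
                        cfg$genome$snp_spacing_mean,
                        cfg$genome$read_length,
                        seed = cfg$seed)
  rs <- cfg$repliseq

  make_arm <- function(delta, stage) {
    land <- rt_landscape(genome, cfg$domains,
                         advance_domain = cfg$advance_domain,
                         advance_delta = delta,
                         allelic_offset = cfg$allelic_offset)
    simulate_repliseq(land, rs$depth_per_fraction, rs$n_replicates,
                      rs$bin_size, rs$k,
                      seed = derive_seed(cfg$seed, stage))
  }

  # wild type: reference distribution and allelic baseline
  wt <- make_arm(0, "wt")
  wt_raw <- compute_rt(wt$counts, cfg$pseudocount, cfg$min_coverage)
  wt_qn <- quantile_normalize(wt_raw, wt_raw)
  wt_delta <- allele_delta(wt_qn)
  files <- c(files, write_binned_counts(wt$counts, out("wt.counts.tsv")))
  files <- c(files, write_rt_bedgraph(wt_qn, out("wt.rt50kb")))

  advances <- list()
  series <- data.frame()
  expr_all <- data.frame()
  windows_files <- character(0)
  for (ci in seq_along(cfg$conditions)) {
    cnd <- cfg$conditions[[ci]]
    arm <- make_arm(cnd$advance_delta, paste0("cond_", cnd$label))
    prof <- quantile_normalize(
      compute_rt(arm$counts, cfg$pseudocount, cfg$min_coverage), wt_raw)
    dlt <- allele_delta(prof)
    adv <- rt_advance(dlt, wt_delta, cfg$advance_domain)
    wins <- window_significance(dlt, wt_delta, rs$n_permutations,
                                seed = derive_seed(cfg$seed,
                                                   paste0("perm_",
                                                          cnd$label)),
                                exclude = cfg$domains[
                                  cfg$domains$class == "switching", ,
                                  drop = FALSE])
    in_dom <- wins$chrom == cfg$advance_domain$chrom &
      wins$start >= cfg$advance_domain$start &
      wins$start < cfg$advance_domain$end
    attr(adv, "n_significant") <- sum(wins$significant[in_dom],
                                      na.rm = TRUE)
    advances[[cnd$label]] <- adv
    wf <- out("windows.", cnd$label, ".tsv")
    write_tsv(wins, wf)
    windows_files <- c(windows_files, wf)

    bru <- simulate_bruseq(
      cfg$genes,
      data.frame(gene = cfg$target_gene, allele = "a1",
                 rate = cnd$target_rate, stringsAsFactors = FALSE),
      cfg$bruseq$library_scale, cfg$bruseq$n_replicates,
      seed = derive_seed(cfg$seed, paste0("bru_", cnd$label)))
    expr <- quantify_nascent(bru, library_size = cfg$bruseq$library_size)
    expr$condition <- cnd$label
    expr_all <- rbind(expr_all, as.data.frame(expr))
    tgt <- expr[expr$gene == cfg$target_gene & expr$allele == "a1", ]
    series <- rbind(series, data.frame(
      condition = cnd$label, covariate = cnd$covariate,
      delta = adv$delta, expression = mean(tgt$rpkm),
      stringsAsFactors = FALSE))
  }

  adv_tab <- do.call(rbind, lapply(names(advances), function(lb) {
    a <- advances[[lb]]
    data.frame(condition = lb, chrom = a$domain$chrom,
               start = a$domain$start, end = a$domain$end,
               delta = a$delta, range_lo = a$replicate_range[1],
               range_hi = a$replicate_range[2], n_windows = a$n_windows,
               n_significant = attr(a, "n_significant"),
               stringsAsFactors = FALSE)
  }))
  files <- c(files, write_tsv(adv_tab, out("advance.tsv")), windows_files,
             write_tsv(expr_all, out("expression.tsv")))

  assoc <- NULL
  if (nrow(series) >= 3) {
    assoc <- advance_vs_expression(series)
    assoc_tab <- assoc$table
    assoc_tab$spearman <- assoc$spearman
    files <- c(files, write_tsv(assoc_tab, out("association.tsv")))
  }

  if (isTRUE(cfg$display$enabled)) {
    land <- rt_landscape(genome, cfg$domains,
                         advance_domain = cfg$advance_domain,
                         advance_delta =
                           cfg$conditions[[length(cfg$conditions)]]$advance_delta,
                         allelic_offset = cfg$allelic_offset)
    dsim <- simulate_repliseq(land, rs$depth_per_fraction, rs$n_replicates,
                              cfg$display$bin_size, rs$k,
                              seed = derive_seed(cfg$seed, "display"))
    draw <- compute_rt(dsim$counts, cfg$pseudocount, cfg$min_coverage)
    dqn <- quantile_normalize(draw, draw)
    dtrk <- scale_rt(smooth_rt(dqn, cfg$display$span_bp),
                     cfg$display$target_halfrange)
    files <- c(files, write_rt_bedgraph(dtrk, out("display.rt5kb")))
  }

  manifest <- write_manifest(files, cfg, cfg$seed, out("manifest.tsv"))
  invisible(list(advances = advances, series = series,
                 association = assoc, expression = expr_all,
                 wt_delta = wt_delta, manifest = manifest))
}

#' Validate a pipeline configuration
#'
#' Checks presence and basic sanity of every field [run_pipeline()] needs,
#' fills documented defaults, and fails with the offending field's name
#' before any computation starts.
#'
#' @param config list or YAML path.
#' @return the validated, default-filled configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  need <- function(name) {
    if (is.null(config[[name]]))
      stop("config validation: missing required field '", name, "'")
    config[[name]]
  }
  cfg <- list()
  cfg$outdir <- need("outdir")
  cfg$seed <- as.integer(need("seed"))
  g <- need("genome")
  if (is.null(g$chromosomes))
    stop("config validation: genome$chromosomes missing")
  cfg$genome <- list(
    chromosomes = do.call(rbind, lapply(g$chromosomes, function(ch)
      data.frame(name = ch$name, length = ch$length,
                 stringsAsFactors = FALSE))),
    snp_spacing_mean = g$snp_spacing_mean %||% 150,
    read_length = g$read_length %||% 100)
  cfg$domains <- do.call(rbind, lapply(need("domains"), function(d)
    data.frame(chrom = d$chrom, start = d$start, end = d$end,
               class = d$class, stringsAsFactors = FALSE)))
  ad <- need("advance_domain")
  cfg$advance_domain <- data.frame(chrom = ad$chrom, start = ad$start,
                                   end = ad$end, stringsAsFactors = FALSE)
  cfg$allelic_offset <- config$allelic_offset %||% 0.1
  rs <- config$repliseq %||% list()
  cfg$repliseq <- list(
    depth_per_fraction = rs$depth_per_fraction %||% 62,
    n_replicates = rs$n_replicates %||% 2,
    bin_size = rs$bin_size %||% 50000,
    k = rs$k %||% 2,
    n_permutations = rs$n_permutations %||% 1000)
  cfg$pseudocount <- config$pseudocount %||% 0.1
  cfg$min_coverage <- config$min_coverage %||% 10
  dp <- config$display %||% list()
  cfg$display <- list(enabled = dp$enabled %||% TRUE,
                      bin_size = dp$bin_size %||% 5000,
                      span_bp = dp$span_bp %||% 300000,
                      target_halfrange = dp$target_halfrange %||% 3)
  cfg$genes <- do.call(rbind, lapply(need("genes"), function(x)
    data.frame(gene = x$gene, chrom = x$chrom, start = x$start,
               end = x$end, strand = x$strand %||% "+",
               stringsAsFactors = FALSE)))
  cfg$target_gene <- need("target_gene")
  if (!cfg$target_gene %in% cfg$genes$gene)
    stop("config validation: target_gene not among genes")
  br <- config$bruseq %||% list()
  cfg$bruseq <- list(library_scale = br$library_scale %||% 1,
                     n_replicates = br$n_replicates %||% 2,
                     library_size = br$library_size %||% 1e6)
  conds <- need("conditions")
  cfg$conditions <- lapply(conds, function(x) {
    if (is.null(x$label) || is.null(x$covariate) ||
        is.null(x$advance_delta) || is.null(x$target_rate))
      stop("config validation: each condition needs label, covariate, ",
           "advance_delta, target_rate")
    x
  })
  if (cfg$repliseq$n_permutations < 100)
    stop("config validation: n_permutations must be >= 100")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage substream seed below 2^31
derive_seed <- function(root, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root) * 2654435 + h * 97 + 12345) %% 2147483647)
}
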