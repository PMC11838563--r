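#' Write / read binned counts as TSV
#'
#' Plain tab-separated tables (`chrom`, `start`, `end`, `allele`,
#' `fraction`, `replicate`, `count`), 0-based half-open coordinates.
#' All writers in the package emit fully deterministic bytes (fixed column
#' order, no timestamps), so reruns with the same seed produce identical
#' files.
#'
#' @param counts a `binned_counts` data.frame.
#' @param path file path.
#' @return `write_binned_counts` the path, invisibly; `read_binned_counts`
#'   a `binned_counts` data.frame.
#' @export
write_binned_counts <- function(counts, path) {
  utils::write.table(as.data.frame(counts)[
    c("chrom", "start", "end", "allele", "fraction", "replicate", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_counts
#' @param bin_size bin width recorded on the returned object; inferred
#'   from the widest bin when `NULL`.
#' @export
read_binned_counts <- function(path, bin_size = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (is.null(bin_size)) bin_size <- max(x$end - x$start)
  attr(x, "bin_size") <- bin_size
  class(x) <- c("binned_counts", "data.frame")
  x
}

#' Write an RT profile as bedGraph tracks
#'
#' One bedGraph per (allele, replicate) track, masked bins omitted; a
#' sidecar `<prefix>.meta.tsv` records bin size and normalization state.
#'
#' @param profile an `rt_profile`.
#' @param prefix output path prefix; files are named
#'   `<prefix>.<allele>.rep<r>.bedGraph`.
#' @return character vector of files written, invisibly.
#' @export
write_rt_bedgraph <- function(profile, prefix) {
  stopifnot(inherits(profile, "rt_profile"))
  written <- character(0)
  track <- unique(profile[c("allele", "replicate")])
  for (i in seq_len(nrow(track))) {
    sel <- profile$allele == track$allele[i] &
      profile$replicate == track$replicate[i] & !profile$masked
    f <- sprintf("%s.%s.rep%s.bedGraph", prefix, track$allele[i],
                 track$replicate[i])
    d <- profile[sel, c("chrom", "start", "end", "rt")]
    d$rt <- sprintf("%.6g", d$rt)
    utils::write.table(d, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, f)
  }
  meta <- sprintf("%s.meta.tsv", prefix)
  writeLines(c("key\tvalue",
               paste0("bin_size\t", rt_bin_size(profile)),
               paste0("state\t", rt_state(profile))), meta)
  invisible(c(written, meta))
}

#' Read a BED3/BED6 interval file
#'
#' @param path BED path (tab-separated, no header, 0-based half-open).
#' @return data.frame `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x) <- c("chrom", "start", "end", "name", "score",
                "strand")[seq_len(ncol(x))]
  x
}

#' Write intervals as BED
#' @param x data.frame with `chrom`, `start`, `end` and optional further
#'   BED columns.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a generic TSV table deterministically
#' @param x data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @export
write_tsv <- function(x, path, digits = 6) {
  x <- as.data.frame(x)
  for (j in seq_along(x))
    if (is.numeric(x[[j]]) && !is.integer(x[[j]]))
      x[[j]] <- sprintf(paste0("%.", digits, "g"), x[[j]])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest with checksums
#'
#' Records each output file's md5 checksum plus the configuration hash
#' and root seed, in a fixed order with no timestamps, so two runs with
#' identical inputs produce byte-identical manifests.
#'
#' @param files character vector of output files (existing).
#' @param config the (already validated) configuration list.
#' @param seed root seed of the run.
#' @param path manifest path.
#' @export
write_manifest <- function(files, config, seed, path) {
  files <- sort(files)
  sums <- tools::md5sum(files)
  cfg_hash <- config_hash(config)
  lines <- c(paste0("config_hash\t", cfg_hash),
             paste0("seed\t", seed),
             paste0(basename(files), "\t", unname(sums)))
  writeLines(lines, path)
  invisible(path)
}

config_hash <- function(config) {
  config$outdir <- NULL  # hash the analysis, not where it lands
  dump <- paste(utils::capture.output(
    utils::str(config[sort(names(config))], give.attr = FALSE)),
    collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(dump, f)
  unname(tools::md5sum(f))
}
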