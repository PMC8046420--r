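# Output writers.  TSV is the canonical format; bedGraph (0-based half-open
# intervals on the synthetic chromosome "sim_locus") is a convenience export
# for genome-browser-style viewing and goes through rtracklayer.

#' Write a profile to TSV or bedGraph
#'
#' TSV columns are `bin` (1-based), `start_bp`, `end_bp` (0-based half-open)
#' and the profile's value columns (`mean`, `sem`, `n_events` for residence
#' profiles; `occupancy`, `occupancy_b` for occupancy profiles), written
#' with 9 significant digits so a written file reads back to the same
#' values.  bedGraph rows use chromosome `sim_locus` and carry the primary
#' value column.
#'
#' @param profile a `residence_profile`, `occupancy_profile`, or data.frame
#'   with `bin`/`start_bp`/`end_bp` plus value columns.
#' @param path output file path.
#' @param format `"tsv"` or `"bedgraph"`.
#' @return `path`, invisibly.
#' @examples
#' prof <- data.frame(bin = 1:3, start_bp = c(0, 100, 200),
#'                    end_bp = c(100, 200, 300), mean = c(0.1, 0.2, 0.3))
#' f <- tempfile(fileext = ".tsv")
#' write_profile(prof, f)
#' @export
write_profile <- function(profile, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(profile))
  if (!all(c("bin", "start_bp", "end_bp") %in% names(profile)))
    stop("write_profile: profile must carry bin/start_bp/end_bp columns")
  if (format == "tsv") {
    out <- profile
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], function(v) signif(v, 9))
    ok <- try(write.table(out, path, sep = "\t", quote = FALSE,
                          row.names = FALSE, fileEncoding = "UTF-8"),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("write_profile: cannot write to '", path, "'")
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE))
      stop("bedGraph export needs the rtracklayer and GenomicRanges packages")
    value <- profile_values(profile)
    gr <- GenomicRanges::GRanges(
      seqnames = "sim_locus",
      ranges = IRanges::IRanges(start = profile$start_bp + 1L,
                                end = profile$end_bp),
      score = signif(value, 9))
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("bedGraph import needs the rtracklayer package")
    gr <- rtracklayer::import(path, format = "bedGraph")
    data.frame(bin = seq_along(gr),
               start_bp = GenomicRanges::start(gr) - 1L,
               end_bp = GenomicRanges::end(gr),
               value = gr$score)
  }
}

#' Write a ChIP-like track as two-column TSV
#'
#' @param track a `chip_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(is.data.frame(track), all(c("bin", "signal") %in% names(track)))
  out <- data.frame(bin = track$bin, value = signif(track$signal, 9))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-bin occupancy (or any two-column) table
#'
#' Reads a two-column TSV (`bin`, `value`), e.g. a custom obstacle
#' occupancy profile, and returns the value vector ordered by bin.
#'
#' @param path input file path.
#' @param n_bins expected number of bins (checked when given).
#' @return Numeric vector of per-bin values.
#' @export
read_bin_table <- function(path, n_bins = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_bin_table: expected two columns (bin, value)")
  v <- df[[2L]][order(df[[1L]])]
  if (!is.null(n_bins) && length(v) != n_bins)
    stop("read_bin_table: expected ", n_bins, " bins, found ", length(v))
  v
}
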