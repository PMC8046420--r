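#' Lattice geometry of the simulated locus
#'
#' Defines the one-dimensional chromatin lattice: `n_bins` bins of
#' `bin_size_bp` base pairs, a gene spanning `gene_start_bin` to
#' `gene_end_bin`, and a termination zone from `term_zone_start_bin` to
#' `term_zone_end_bin`.  The defaults describe a 10-kbp locus of 100 bins of
#' 100 bp, with a 2-kbp gene on bins 1--20 and a termination zone covering
#' every bin from 20 onwards (RNAP may unbind there, and the backtrack model
#' raises its backtracking rate there).
#'
#' Bin indices are 1-based and inclusive.  For export, bin `i` maps to the
#' 0-based half-open genomic interval `[(i-1)*bin_size_bp, i*bin_size_bp)`.
#'
#' @param n_bins number of lattice bins (>= 2).
#' @param bin_size_bp bin width in base pairs.
#' @param gene_start_bin,gene_end_bin first and last bin of the gene.
#' @param term_zone_start_bin,term_zone_end_bin first and last bin of the
#'   termination zone.
#' @return An object of class `lattice_config`.
#' @examples
#' lat <- lattice_config()
#' lat$n_bins * lat$bin_size_bp  # 10 kbp
#' @export
lattice_config <- function(n_bins = 100L, bin_size_bp = 100L,
                           gene_start_bin = 1L, gene_end_bin = 20L,
                           term_zone_start_bin = 20L,
                           term_zone_end_bin = n_bins) {
  lat <- list(n_bins = as.integer(n_bins),
              bin_size_bp = as.integer(bin_size_bp),
              gene_start_bin = as.integer(gene_start_bin),
              gene_end_bin = as.integer(gene_end_bin),
              term_zone_start_bin = as.integer(term_zone_start_bin),
              term_zone_end_bin = as.integer(term_zone_end_bin))
  class(lat) <- "lattice_config"
  validate_lattice(lat)
}

validate_lattice <- function(lat) {
  stopifnot(inherits(lat, "lattice_config"))
  with(lat, {
    if (is.na(n_bins) || n_bins < 2L)
      stop("lattice_config: n_bins must be >= 2, got ", n_bins)
    if (is.na(bin_size_bp) || bin_size_bp < 1L)
      stop("lattice_config: bin_size_bp must be >= 1, got ", bin_size_bp)
    if (!(1L <= gene_start_bin && gene_start_bin < gene_end_bin))
      stop("lattice_config: need 1 <= gene_start_bin < gene_end_bin ",
           "(got ", gene_start_bin, ", ", gene_end_bin, ")")
    if (!(gene_end_bin <= term_zone_start_bin))
      stop("lattice_config: gene_end_bin must be <= term_zone_start_bin")
    if (!(term_zone_start_bin <= term_zone_end_bin &&
          term_zone_end_bin <= n_bins))
      stop("lattice_config: need term_zone_start_bin <= term_zone_end_bin",
           " <= n_bins")
  })
  lat
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf("<lattice_config> %d bins x %d bp = %.1f kbp\n",
              x$n_bins, x$bin_size_bp, x$n_bins * x$bin_size_bp / 1000))
  cat(sprintf("  gene: bins %d-%d; termination zone: bins %d-%d\n",
              x$gene_start_bin, x$gene_end_bin,
              x$term_zone_start_bin, x$term_zone_end_bin))
  invisible(x)
}

# genomic coordinates of bin i: 0-based half-open [(i-1)*w, i*w)
bin_coords <- function(lattice, bins = seq_len(lattice$n_bins)) {
  w <- lattice$bin_size_bp
  data.frame(bin = bins, start_bp = (bins - 1L) * w, end_bp = bins * w)
}
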