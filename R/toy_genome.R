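#' Generate a toy experimental/calibration genome pair
#'
#' Builds a pair of small random genomes playing the roles of the experimental
#' organism (e.g. *S. cerevisiae*) and the spike-in calibration organism
#' (e.g. *C. glabrata*) in calibrated ChIP-seq. Sequences are resampled until
#' every substring of length `read_length` occurs at most once across both
#' strands of both genomes combined, which guarantees that error-free reads of
#' that length map back to a unique location by exact matching. One anchor
#' coordinate per experimental chromosome (the CDEIII-like element used to
#' centre meta-profiles) is placed at the chromosome midpoint.
#'
#' @param n_chrom number of experimental chromosomes.
#' @param chrom_length length of each experimental chromosome in bp
#'   (must exceed `2 * read_length`; at most 200 kb).
#' @param n_cal_chrom number of calibration chromosomes.
#' @param cal_length length of each calibration chromosome in bp.
#' @param read_length read length in bp; also the k used for the unique
#'   k-mer guarantee.
#' @param seed integer RNG seed; identical arguments and seed give identical
#'   genomes.
#' @param max_tries resampling attempts before giving up on uniqueness.
#'
#' @return An object of class `toy_genome_pair`: a list with elements
#'   `experimental` and `calibration` ([Biostrings::DNAStringSet] of
#'   chromosomes with disjoint names), `anchors` (named integer vector,
#'   1-based, one per experimental chromosome), and `read_length`.
#' @seealso [simulate_chip_experiment()], [assign_reads_sequential()]
#' @examples
#' pair <- make_toy_genome_pair(1, 1000, 1, 1000, read_length = 50, seed = 7)
#' pair$anchors
#' @export
make_toy_genome_pair <- function(n_chrom, chrom_length, n_cal_chrom, cal_length,
                                 read_length, seed, max_tries = 20L) {
  if (!is_count(n_chrom) || !is_count(n_cal_chrom)) {
    stop("chromosome counts must be positive integers")
  }
  if (!is_count(chrom_length) || !is_count(cal_length) || !is_count(read_length)) {
    stop("chromosome lengths and read_length must be positive integers")
  }
  if (chrom_length > 2e5 || cal_length > 2e5) {
    stop("chromosome lengths must stay at desk scale (<= 200 kb each)")
  }
  if (chrom_length <= 2 * read_length || cal_length <= 2 * read_length) {
    stop("chromosome lengths must exceed 2 * read_length")
  }

  exp_names <- sprintf("chr%02d", seq_len(n_chrom))
  cal_names <- sprintf("cal%02d", seq_len(n_cal_chrom))

  random_chrom <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }

  pair <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      exp_seqs <- vapply(seq_len(n_chrom), function(i) random_chrom(chrom_length), "")
      cal_seqs <- vapply(seq_len(n_cal_chrom), function(i) random_chrom(cal_length), "")
      if (kmers_unique(c(exp_seqs, cal_seqs), read_length)) {
        names(exp_seqs) <- exp_names
        names(cal_seqs) <- cal_names
        anchors <- setNames(rep(as.integer(chrom_length %/% 2L), n_chrom), exp_names)
        return(structure(
          list(
            experimental = Biostrings::DNAStringSet(exp_seqs),
            calibration  = Biostrings::DNAStringSet(cal_seqs),
            anchors      = anchors,
            read_length  = as.integer(read_length)
          ),
          class = "toy_genome_pair"
        ))
      }
    }
    stop("genome too repetitive: could not enforce unique ", read_length,
         "-mers after ", max_tries, " attempts")
  })
  validate_toy_genome_pair(pair)
  pair
}

# TRUE iff every k-mer occurs at most once across both strands of all seqs.
kmers_unique <- function(seqs, k) {
  fwd <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (length(fwd) == 0L) return(TRUE)
  all_kmers <- c(fwd, reverse_complement(fwd))
  anyDuplicated(all_kmers) == 0L
}

#' Validate the invariants of a toy genome pair
#'
#' Checks chromosome-name disjointness, in-bounds anchors (one per
#' experimental chromosome), and the unique k-mer guarantee at
#' `read_length`. Called by [make_toy_genome_pair()] and useful after
#' reading a pair back from disk.
#'
#' @param pair a `toy_genome_pair`.
#' @return `pair`, invisibly; errors if any invariant is violated.
#' @export
validate_toy_genome_pair <- function(pair) {
  stopifnot(inherits(pair, "toy_genome_pair"))
  exp_names <- names(pair$experimental)
  cal_names <- names(pair$calibration)
  if (length(intersect(exp_names, cal_names)) > 0L) {
    stop("chromosome names must be disjoint between the two genomes")
  }
  if (!identical(sort(names(pair$anchors)), sort(exp_names))) {
    stop("anchors must name every experimental chromosome exactly once")
  }
  lens <- Biostrings::width(pair$experimental)[match(names(pair$anchors), exp_names)]
  if (any(pair$anchors < 1L | pair$anchors > lens)) {
    stop("every anchor must lie within its chromosome (1 <= anchor <= length)")
  }
  seqs <- c(as.character(pair$experimental), as.character(pair$calibration))
  if (!kmers_unique(seqs, pair$read_length)) {
    stop("genome too repetitive: duplicate ", pair$read_length, "-mers present")
  }
  invisible(pair)
}

#' @export
print.toy_genome_pair <- function(x, ...) {
  cat("Toy genome pair (read_length =", x$read_length, "bp)\n")
  cat("  experimental:", length(x$experimental), "chromosome(s),",
      sum(Biostrings::width(x$experimental)), "bp total\n")
  cat("  calibration: ", length(x$calibration), "chromosome(s),",
      sum(Biostrings::width(x$calibration)), "bp total\n")
  cat("  anchors:", paste(names(x$anchors), x$anchors, sep = ":", collapse = " "), "\n")
  invisible(x)
}

# Light structural check for hot paths: class, name disjointness and anchor
# bounds only. Full k-mer validation (O(genome)) stays in the constructor
# and in read_genome_pair().
check_pair_structure <- function(pair) {
  if (!inherits(pair, "toy_genome_pair")) stop("`pair` must be a toy_genome_pair")
  if (length(intersect(names(pair$experimental), names(pair$calibration))) > 0L) {
    stop("chromosome names must be disjoint between the two genomes")
  }
  lens <- genome_lengths(pair$experimental)
  if (!all(names(pair$anchors) %in% names(lens)) ||
      any(pair$anchors < 1L | pair$anchors > lens[names(pair$anchors)])) {
    stop("every anchor must lie within its experimental chromosome")
  }
  invisible(pair)
}

# Lengths of all chromosomes of one genome, named.
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}
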