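#' Assign reads to genomes by the sequential two-genome scheme
#'
#' Reproduces, at desk scale, the calibrated ChIP-seq alignment order: each
#' read is tested against the calibration (spike-in) genome first and is
#' assigned there iff its sequence or reverse complement exact-matches exactly
#' one location; any read not uniquely matching the calibration genome is then
#' tested against the experimental genome under the same unique-exact-match
#' rule. Reads matching neither genome, or matching more than one location in
#' the genome under test, are left unassigned. Reverse-strand matches are
#' reported at the leftmost base on the forward coordinate system (SAM
#' convention). Input order is preserved.
#'
#' The internal mapper is exact-match because synthetic reads are error-free;
#' alignments produced externally by a gapped aligner can be ingested instead
#' via [read_sam_assignments()].
#'
#' @param reads a data.frame with columns `id` (or `read_id`) and `sequence`
#'   (e.g. from [simulate_chip_experiment()] or [read_reads_fastq()]), or a
#'   named character vector of read sequences.
#' @param pair the [make_toy_genome_pair()] genome pair.
#' @return A data.frame of class `assigned_reads` with columns `read_id`,
#'   `genome` ("experimental", "calibration" or "unassigned"), `chrom`,
#'   `start` (1-based), `strand` and `aligned_length`; locus columns are `NA`
#'   for unassigned reads.
#' @examples
#' pair <- make_toy_genome_pair(1, 500, 1, 500, read_length = 30, seed = 3)
#' rd <- as.character(pair$experimental[[1]][101:130])
#' assign_reads_sequential(data.frame(id = "r1", sequence = rd), pair)
#' @export
assign_reads_sequential <- function(reads, pair) {
  check_pair_structure(pair)
  if (is.character(reads)) {
    ids <- if (is.null(names(reads))) sprintf("read_%06d", seq_along(reads)) else names(reads)
    seqs <- unname(reads)
  } else {
    stopifnot(is.data.frame(reads))
    id_col <- if ("id" %in% names(reads)) "id" else "read_id"
    stopifnot(id_col %in% names(reads), "sequence" %in% names(reads))
    ids <- as.character(reads[[id_col]])
    seqs <- as.character(reads$sequence)
  }

  n <- length(seqs)
  out <- data.frame(
    read_id = ids,
    genome = rep("unassigned", n),
    chrom = rep(NA_character_, n),
    start = rep(NA_integer_, n),
    strand = rep(NA_character_, n),
    aligned_length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(structure(out, class = c("assigned_reads", "data.frame")))

  min_chrom <- min(genome_lengths(pair$experimental), genome_lengths(pair$calibration))
  too_long <- nchar(seqs) > min_chrom
  if (any(too_long)) {
    warning(sum(too_long), " read(s) longer than a chromosome; left unassigned")
  }

  # reads of equal length share one exact-match index per genome
  for (len in unique(nchar(seqs[!too_long]))) {
    sel <- which(nchar(seqs) == len & !too_long)
    cal_hit <- unique_exact_matches(seqs[sel], pair$calibration, len)
    take_cal <- !is.na(cal_hit$chrom)
    out$genome[sel[take_cal]] <- "calibration"
    out$chrom[sel[take_cal]] <- cal_hit$chrom[take_cal]
    out$start[sel[take_cal]] <- cal_hit$pos[take_cal]
    out$strand[sel[take_cal]] <- cal_hit$strand[take_cal]

    rest <- sel[!take_cal]
    if (length(rest) > 0L) {
      exp_hit <- unique_exact_matches(seqs[rest], pair$experimental, len)
      take_exp <- !is.na(exp_hit$chrom)
      out$genome[rest[take_exp]] <- "experimental"
      out$chrom[rest[take_exp]] <- exp_hit$chrom[take_exp]
      out$start[rest[take_exp]] <- exp_hit$pos[take_exp]
      out$strand[rest[take_exp]] <- exp_hit$strand[take_exp]
    }
  }
  structure(out, class = c("assigned_reads", "data.frame"))
}

# For each query, find its unique exact match (either strand) in `genome`.
# Returns chrom/pos/strand vectors with NA where the query matches zero or
# more than one location over both strands combined.
unique_exact_matches <- function(queries, genome, k) {
  idx <- kmer_index(genome, k)
  if (nrow(idx) == 0L) {
    na <- rep(NA_character_, length(queries))
    return(list(chrom = na, pos = rep(NA_integer_, length(queries)), strand = na))
  }
  look <- function(q) {
    idx[list(q), on = "kmer", mult = "first",
        list(chrom = chrom, pos = pos, n = n)]
  }
  fwd <- look(queries)
  rev <- look(reverse_complement(queries))
  n_fwd <- ifelse(is.na(fwd$n), 0L, fwd$n)
  n_rev <- ifelse(is.na(rev$n), 0L, rev$n)
  total <- n_fwd + n_rev
  uniq <- total == 1L
  chrom <- ifelse(uniq, ifelse(n_fwd == 1L, fwd$chrom, rev$chrom), NA_character_)
  pos <- ifelse(uniq, ifelse(n_fwd == 1L, fwd$pos, rev$pos), NA_integer_)
  strand <- ifelse(uniq, ifelse(n_fwd == 1L, "+", "-"), NA_character_)
  list(chrom = chrom, pos = as.integer(pos), strand = strand)
}

# Forward-strand k-mer index of a genome: one row per (kmer occurrence),
# annotated with the total occurrence count n of that kmer.
kmer_index <- function(genome, k) {
  pieces <- lapply(names(genome), function(chrom) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table(kmer = substring(s, pos, pos + k - 1L), chrom = chrom, pos = pos)
  })
  idx <- data.table::rbindlist(pieces)
  idx[, n := .N, by = kmer]
  setkeyv(idx, "kmer")
  idx
}

#' Tally the four calibration counts
#'
#' Counts uniquely assigned reads in each (sample, genome) cell: `W_x` and
#' `W_c` for WCE reads on the experimental and calibration genomes, `IP_x`
#' and `IP_c` for IP reads. Unassigned reads are excluded from every count.
#' These four totals define the occupancy ratio (see [occupancy_ratio()]).
#'
#' @param assignments_ip,assignments_wce `assigned_reads` data.frames for the
#'   IP and WCE samples.
#' @return A `calibration_counts` object.
#' @export
tally_calibration_counts <- function(assignments_ip, assignments_wce) {
  count_cell <- function(a, genome) {
    if (is.null(a) || nrow(a) == 0L) return(0L)
    sum(a$genome == genome)
  }
  calibration_counts(
    W_x  = count_cell(assignments_wce, "experimental"),
    W_c  = count_cell(assignments_wce, "calibration"),
    IP_x = count_cell(assignments_ip, "experimental"),
    IP_c = count_cell(assignments_ip, "calibration")
  )
}

#' Construct a calibration-count object
#'
#' @param W_x,W_c WCE reads uniquely assigned to the experimental and
#'   calibration genomes.
#' @param IP_x,IP_c IP reads uniquely assigned to the experimental and
#'   calibration genomes.
#' @return A `calibration_counts` object (list with the four counts).
#' @export
calibration_counts <- function(W_x, W_c, IP_x, IP_c) {
  counts <- list(W_x = W_x, W_c = W_c, IP_x = IP_x, IP_c = IP_c)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]], positive = FALSE)) {
      stop("count ", nm, " must be a non-negative integer")
    }
  }
  structure(lapply(counts, as.numeric), class = "calibration_counts")
}

#' @export
print.calibration_counts <- function(x, ...) {
  cat("Calibration counts: W_x =", x$W_x, " W_c =", x$W_c,
      " IP_x =", x$IP_x, " IP_c =", x$IP_c, "\n")
  invisible(x)
}
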