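# Text-format readers and writers for every external interface of the
# pipeline: FASTA genomes, FASTQ reads, BED anchors, SAM assignments,
# TSV lanes / absorbance series / meta-profiles, JSON calibration reports.

#' Write a toy genome pair to a directory
#'
#' Writes `experimental.fasta` and `calibration.fasta` (one record per
#' chromosome) plus `anchors.bed` (6-column BED, 0-based half-open, each
#' anchor as a 1-bp interval).
#'
#' @param pair a [make_toy_genome_pair()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_pair <- function(pair, dir) {
  validate_toy_genome_pair(pair)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(pair$experimental, file.path(dir, "experimental.fasta"))
  Biostrings::writeXStringSet(pair$calibration, file.path(dir, "calibration.fasta"))
  write_anchors_bed(pair$anchors, file.path(dir, "anchors.bed"))
  invisible(dir)
}

#' Read a toy genome pair back from a directory
#'
#' @param dir directory written by [write_genome_pair()].
#' @param read_length read length the pair guarantees unique k-mers for.
#' @return A validated `toy_genome_pair`.
#' @export
read_genome_pair <- function(dir, read_length) {
  pair <- structure(
    list(
      experimental = Biostrings::readDNAStringSet(file.path(dir, "experimental.fasta")),
      calibration  = Biostrings::readDNAStringSet(file.path(dir, "calibration.fasta")),
      anchors      = read_anchors_bed(file.path(dir, "anchors.bed")),
      read_length  = as.integer(read_length)
    ),
    class = "toy_genome_pair"
  )
  validate_toy_genome_pair(pair)
  pair
}

#' Write anchors as 6-column BED
#'
#' Each anchor becomes a 1-bp interval in 0-based half-open coordinates.
#'
#' @param anchors named integer vector of 1-based anchor positions.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_anchors_bed <- function(anchors, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = names(anchors),
    ranges = IRanges::IRanges(start = unname(anchors), width = 1L),
    strand = "+",
    name = paste0(names(anchors), "_anchor"),
    score = 0L
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Read anchors from a BED file
#'
#' @param file BED path with one 1-bp anchor interval per chromosome.
#' @return Named integer vector of 1-based anchor positions.
#' @export
read_anchors_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (anyDuplicated(chroms)) stop("more than one anchor for a chromosome in ", file)
  setNames(GenomicRanges::start(gr), chroms)
}

#' Write simulated reads as FASTQ
#'
#' Qualities are uniform 'I' (error-free synthetic reads).
#'
#' @param reads data.frame with `id` and `sequence` columns.
#' @param file output path.
#' @param sample optional value of the `sample` column to subset on
#'   (e.g. `"IP"`).
#' @return `file`, invisibly.
#' @export
write_reads_fastq <- function(reads, file, sample = NULL) {
  if (!is.null(sample)) reads <- reads[reads$sample == sample, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, file, format = "fastq", qualities = quals)
  invisible(file)
}

#' Read a FASTQ file into an id/sequence data.frame
#'
#' @param file FASTQ path.
#' @return data.frame with columns `id` and `sequence`, suitable for
#'   [assign_reads_sequential()].
#' @export
read_reads_fastq <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(
    id = sub("\\s.*", "", names(seqs)),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write assignments of one genome as SAM
#'
#' Emits a minimal single-end SAM file (header `@SQ` lines for the chosen
#' genome, flag 0/16 for strand, MAPQ 255, full-length match CIGAR),
#' mirroring the pipeline convention of one alignment file per genome;
#' unassigned reads go to a separate FASTQ via [write_unassigned_fastq()].
#'
#' @param assignments an `assigned_reads` data.frame.
#' @param pair the genome pair.
#' @param genome `"experimental"` or `"calibration"`: which genome's
#'   assignments to write.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_assignment_sam <- function(assignments, pair,
                                 genome = c("experimental", "calibration"), file) {
  genome <- match.arg(genome)
  lens <- genome_lengths(pair[[genome]])
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens)
  )
  rows <- assignments[assignments$genome == genome, , drop = FALSE]
  records <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
    rows$read_id,
    ifelse(rows$strand == "-", 16L, 0L),
    rows$chrom, rows$start, rows$aligned_length
  )
  writeLines(c(header, records), file)
  invisible(file)
}

#' Write unassigned reads as FASTQ
#'
#' Mirrors saving unaligned reads to a separate file in the sequential
#' alignment scheme.
#'
#' @param reads the original reads data.frame (`id`, `sequence`).
#' @param assignments the matching `assigned_reads`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_unassigned_fastq <- function(reads, assignments, file) {
  id_col <- if ("id" %in% names(reads)) "id" else "read_id"
  unass <- assignments$read_id[assignments$genome == "unassigned"]
  write_reads_fastq(reads[reads[[id_col]] %in% unass, , drop = FALSE], file)
}

#' Ingest externally produced SAM alignments
#'
#' Alternative input path for alignments from a real (gapped) aligner. The
#' header's `@SQ` lines must name chromosomes of exactly one of the two
#' genomes; records that are unmapped or fall below the MAPQ floor are
#' treated as unassigned. SAM 1-based POS is adopted unchanged; aligned
#' length is the CIGAR width along the reference.
#'
#' @param file SAM path.
#' @param pair the genome pair the alignments refer to.
#' @param mapq_floor minimum MAPQ for an assignment (default 10).
#' @return An `assigned_reads` data.frame whose `genome` column is the
#'   genome named by the header (or `"unassigned"`).
#' @export
read_sam_assignments <- function(file, pair, mapq_floor = 10) {
  bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  targets <- names(Rsamtools::scanBamHeader(bam)[[1L]]$targets)
  in_exp <- all(targets %in% names(pair$experimental))
  in_cal <- all(targets %in% names(pair$calibration))
  if (in_exp == in_cal) {
    stop("SAM header must name chromosomes of exactly one of the two genomes")
  }
  genome_label <- if (in_exp) "experimental" else "calibration"

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  mapped <- !bitwAnd(rec$flag, 4L) & !is.na(rec$pos) &
    !is.na(rec$mapq) & rec$mapq >= mapq_floor
  alen <- rep(NA_integer_, length(rec$qname))
  alen[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[mapped])
  data.frame(
    read_id = rec$qname,
    genome = ifelse(mapped, genome_label, "unassigned"),
    chrom = ifelse(mapped, as.character(rec$rname), NA_character_),
    start = ifelse(mapped, rec$pos, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+"), NA_character_),
    aligned_length = alen,
    stringsAsFactors = FALSE
  ) -> out
  structure(out, class = c("assigned_reads", "data.frame"))
}

#' Write replicate lanes as TSV
#'
#' One row per replicate, one column per band (raw intensities).
#'
#' @param lanes list of [quantify_lane()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_lanes_tsv <- function(lanes, file) {
  mat <- do.call(rbind, lapply(lanes, function(ln) ln$bands))
  df <- data.frame(replicate = seq_along(lanes), mat, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read replicate lanes from TSV
#'
#' @param file path written by [write_lanes_tsv()].
#' @return List of `lane_quant` objects.
#' @export
read_lanes_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE)
  bands <- setdiff(names(df), "replicate")
  lapply(seq_len(nrow(df)), function(i) {
    quantify_lane(setNames(as.numeric(df[i, bands]), bands))
  })
}

#' Write an absorbance series as TSV
#'
#' @param series an `absorbance_series` (`time`, `au`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_series_tsv <- function(series, file) {
  write.table(series[, c("time", "au")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an absorbance series from TSV
#'
#' @param file path with `time` and `au` columns.
#' @return An `absorbance_series` data.frame.
#' @export
read_series_tsv <- function(file) {
  df <- read.delim(file)
  stopifnot(all(c("time", "au") %in% names(df)))
  structure(df[, c("time", "au")], class = c("absorbance_series", "data.frame"))
}

#' Write a meta-profile as TSV
#'
#' Columns `offset`, `value`, `n_contributing`.
#'
#' @param profile an [anchor_meta_profile()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_meta_profile_tsv <- function(profile, file) {
  write.table(as.data.frame(profile), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a calibration report as JSON
#'
#' Records the four calibration counts, the occupancy ratio and the
#' per-million denominator.
#'
#' @param counts a [calibration_counts()] object.
#' @param calib the matching [occupancy_ratio()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_calibration_report <- function(counts, calib, file) {
  jsonlite::write_json(
    list(
      counts = counts[c("W_x", "W_c", "IP_x", "IP_c")],
      occupancy_ratio = calib$OR,
      per_million_denominator = calib$total_ip_experimental_reads
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
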