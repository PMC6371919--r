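#' Specify an anchor-centred IP occupancy profile
#'
#' Describes the expected IP enrichment around each anchor: a uniform
#' background with a peak of `peak_enrichment`-fold over background at the
#' anchor, decaying linearly back to background over `decay_span` bp on either
#' side. The 30 kb default matches the distance over which centromere-loaded
#' cohesin spreads into peri-centric sequences.
#'
#' @param background mean background depth weight (dimensionless, >= 0).
#' @param peak_enrichment fold enrichment over background at the anchor (>= 1).
#' @param decay_span bp over which enrichment falls linearly to background
#'   (>= 0; 0 confines the peak to the anchor base itself).
#' @return An `occupancy_profile_spec` object.
#' @examples
#' spec <- occupancy_profile_spec(peak_enrichment = 10)
#' profile_value(spec, c(-40000, 0, 15000, 40000))
#' @export
occupancy_profile_spec <- function(background = 1, peak_enrichment = 10,
                                   decay_span = 30000) {
  stopifnot(is.numeric(background), length(background) == 1L, background >= 0)
  stopifnot(is.numeric(peak_enrichment), length(peak_enrichment) == 1L,
            peak_enrichment >= 1)
  stopifnot(is.numeric(decay_span), length(decay_span) == 1L, decay_span >= 0)
  structure(
    list(background = background, peak_enrichment = peak_enrichment,
         decay_span = decay_span),
    class = "occupancy_profile_spec"
  )
}

#' Evaluate an occupancy profile at offsets from the anchor
#'
#' @param spec an [occupancy_profile_spec()].
#' @param offset numeric vector of signed distances from the anchor in bp.
#' @return Profile weight at each offset; equals `background` wherever
#'   `abs(offset) >= decay_span`.
#' @export
profile_value <- function(spec, offset) {
  stopifnot(inherits(spec, "occupancy_profile_spec"))
  if (spec$decay_span == 0) {
    shape <- as.numeric(offset == 0)
  } else {
    shape <- pmax(0, 1 - abs(offset) / spec$decay_span)
  }
  spec$background * (1 + (spec$peak_enrichment - 1) * shape)
}

#' Simulate a calibrated ChIP-seq experiment
#'
#' Draws error-free single-end reads for an IP sample and a whole-cell-extract
#' (WCE) sample from a mixture of experimental and spike-in calibration cells.
#' WCE reads start uniformly across both genomes, with the genome share
#' proportional to `cell_ratio_exp_to_cal` times genome size (the 3:1 default
#' mirrors mixing 15 OD units of experimental cells with 5 OD units of
#' calibration cells). IP reads from the experimental genome are drawn with
#' per-base weight given by the anchor-centred `profile` (evaluated at the
#' read midpoint so the depth peak sits on the anchor); IP reads from the
#' calibration genome follow a uniform profile at background level, the
#' default assumption for spike-in chromatin.
#'
#' @param pair a [make_toy_genome_pair()] result.
#' @param profile an [occupancy_profile_spec()] for the experimental IP.
#' @param cell_ratio_exp_to_cal experimental:calibration cell ratio (> 0).
#' @param n_reads_ip,n_reads_wce number of reads to draw per sample.
#' @param seed integer RNG seed.
#' @return A data.frame of simulated reads with columns `id`, `sequence`,
#'   `sample` ("IP"/"WCE"), and ground-truth columns `truth_genome`
#'   ("experimental"/"calibration"), `truth_chrom`, `truth_pos` (1-based
#'   leftmost base) and `truth_strand`.
#' @examples
#' pair <- make_toy_genome_pair(1, 2000, 1, 2000, read_length = 50, seed = 1)
#' reads <- simulate_chip_experiment(pair, occupancy_profile_spec(decay_span = 500),
#'                                   cell_ratio_exp_to_cal = 3,
#'                                   n_reads_ip = 100, n_reads_wce = 100, seed = 2)
#' table(reads$sample, reads$truth_genome)
#' @export
simulate_chip_experiment <- function(pair, profile = occupancy_profile_spec(),
                                     cell_ratio_exp_to_cal = 3,
                                     n_reads_ip, n_reads_wce, seed) {
  check_pair_structure(pair)
  stopifnot(inherits(profile, "occupancy_profile_spec"))
  stopifnot(is.numeric(cell_ratio_exp_to_cal), cell_ratio_exp_to_cal > 0)
  if (!is_count(n_reads_ip) || !is_count(n_reads_wce)) {
    stop("read counts must be positive integers")
  }
  if (length(pair$experimental) == 0L || length(pair$calibration) == 0L ||
      any(genome_lengths(pair$experimental) == 0L) ||
      any(genome_lengths(pair$calibration) == 0L)) {
    stop("empty genome")
  }

  k <- pair$read_length
  starts <- start_table(pair, profile, cell_ratio_exp_to_cal)

  with_seed(seed, {
    ip  <- draw_reads(pair, starts, starts$w_ip,  n_reads_ip,  "IP",  k)
    wce <- draw_reads(pair, starts, starts$w_wce, n_reads_wce, "WCE", k)
    rbind(ip, wce)
  })
}

# Enumerate every valid read start of both genomes with its IP and WCE
# sampling weight.
start_table <- function(pair, profile, cell_ratio) {
  k <- pair$read_length
  per_genome <- function(genome, genome_label, cell_weight) {
    lens <- genome_lengths(genome)
    do.call(rbind, lapply(names(lens), function(chrom) {
      n_start <- lens[[chrom]] - k + 1L
      pos <- seq_len(n_start)
      if (genome_label == "experimental") {
        mid <- pos + (k - 1L) %/% 2L
        w_ip <- cell_weight * profile_value(profile, mid - pair$anchors[[chrom]])
      } else {
        w_ip <- rep(cell_weight * profile$background, n_start)
      }
      data.frame(
        genome = genome_label, chrom = chrom, pos = pos,
        w_ip = w_ip, w_wce = rep(cell_weight, n_start),
        stringsAsFactors = FALSE
      )
    }))
  }
  rbind(
    per_genome(pair$experimental, "experimental", cell_ratio),
    per_genome(pair$calibration, "calibration", 1)
  )
}

draw_reads <- function(pair, starts, weights, n, sample_label, k) {
  if (sum(weights) <= 0) {
    stop("total sampling weight is zero for the ", sample_label,
         " sample; increase the profile background")
  }
  idx <- sample.int(nrow(starts), n, replace = TRUE, prob = weights)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom <- starts$chrom[idx]
  pos <- starts$pos[idx]
  genome <- starts$genome[idx]
  seqs <- character(n)
  for (g in c("experimental", "calibration")) {
    sel <- genome == g
    if (!any(sel)) next
    chrom_seqs <- as.character(pair[[g]])
    seqs[sel] <- substring(chrom_seqs[chrom[sel]], pos[sel], pos[sel] + k - 1L)
  }
  rev_sel <- strand == "-"
  if (any(rev_sel)) seqs[rev_sel] <- reverse_complement(seqs[rev_sel])
  data.frame(
    id = sprintf("%s_%07d", sample_label, seq_len(n)),
    sequence = seqs,
    sample = sample_label,
    truth_genome = genome,
    truth_chrom = chrom,
    truth_pos = as.integer(pos),
    truth_strand = strand,
    stringsAsFactors = FALSE
  )
}
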