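# Independent brute-force oracles and shared fixtures. Every oracle here
# recomputes a quantity by direct enumeration / scanning, deliberately
# avoiding the package's indexed or closed-form code paths.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All (chrom, pos, strand) exact matches of `q` in a DNAStringSet genome,
# by scanning every position of every chromosome on both strands.
oracle_scan_genome <- function(q, genome) {
  hits <- list()
  rc <- revcomp(q)
  k <- nchar(q)
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    if (L < k) next
    subs <- substring(s, 1:(L - k + 1L), k:L)
    for (p in which(subs == q)) {
      hits[[length(hits) + 1L]] <- list(chrom = chrom, pos = p, strand = "+")
    }
    for (p in which(subs == rc)) {
      hits[[length(hits) + 1L]] <- list(chrom = chrom, pos = p, strand = "-")
    }
  }
  hits
}

# Sequential assignment of one read by exhaustive scanning: calibration
# genome first, unique hits only, then the experimental genome.
oracle_assign_read <- function(q, pair) {
  for (g in c("calibration", "experimental")) {
    hits <- oracle_scan_genome(q, pair[[g]])
    if (length(hits) == 1L) {
      return(list(genome = g, chrom = hits[[1L]]$chrom,
                  start = hits[[1L]]$pos, strand = hits[[1L]]$strand))
    }
  }
  list(genome = "unassigned", chrom = NA_character_,
       start = NA_integer_, strand = NA_character_)
}

# Per-base depth by counting covering intervals at each position.
oracle_pileup <- function(starts, lens, L) {
  vapply(seq_len(L), function(i) sum(starts <= i & i <= starts + lens - 1L), 0)
}

# Per-offset mean across chromosomes by direct looping.
oracle_meta_profile <- function(tracks, anchors, W) {
  offsets <- -W:W
  vapply(offsets, function(d) {
    vals <- c()
    for (tr in tracks) {
      p <- anchors[[tr$chrom]] + d
      if (p >= 1L && p <= tr$length) vals <- c(vals, tr$depth[p])
    }
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, 0)
}

# Expected CM/CD detectable fractions by exhaustive enumeration over all
# 2^3 crosslink outcomes per copy and all ordered partner tuples.
oracle_species_fractions <- function(model) {
  ifs <- ring_interfaces()
  e <- model$efficiencies[ifs]
  circ <- vapply(model$copies, function(cp) {
    if (!setequal(cp$interfaces, ifs)) return(0)
    p <- 0
    for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
      outcome <- c(o1, o2, o3)
      prob <- prod(ifelse(outcome == 1, e, 1 - e))
      if (all(outcome == 1)) p <- p + prob
    }
    p
  }, 0)
  tagged <- which(vapply(model$copies, function(cp) isTRUE(cp$tagged), TRUE))
  n <- length(model$copies)
  k <- model$k
  cd_per_tag <- vapply(tagged, function(t) {
    if (k == 1L) return(circ[t])
    tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), k - 1L)))
    mean(apply(tuples, 1L, function(tp) circ[t] * prod(circ[tp])))
  }, 0)
  list(CM_detectable = model$p_CM * mean(circ[tagged]),
       CD_detectable = model$p_CD * mean(cd_per_tag))
}

# Random stoichiometry model for property-style tests.
random_model <- function(k = sample(1:3, 1L), p_CM = runif(1), p_CD = runif(1)) {
  n <- sample(1:4, 1L)
  copies <- lapply(seq_len(n), function(i) {
    ifs <- ring_interfaces()
    if (runif(1) < 0.5) ifs <- sample(ifs, sample(0:2, 1L))
    ring_copy(interfaces = ifs, tagged = FALSE)
  })
  copies[[sample(n, 1L)]]$tagged <- TRUE
  stoichiometry_model(
    copies = copies,
    efficiencies = setNames(runif(3), ring_interfaces()),
    k = k, p_CM = p_CM, p_CD = p_CD
  )
}

# Shared small genome pair, built once per test run.
tiny_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_genome_pair(2, 3000, 1, 2000, read_length = 40, seed = 42)
    }
    cache
  }
})

# Hand-built pair (bypassing the unique k-mer constructor) whose genomes
# deliberately share or repeat k-mers, for exercising the assignment rules.
# Layout, with read length 10:
#   cal01  = CALSEQ
#   chr01  = SHARED .. DUPA .. DUPA   (DUPA occurs twice)
#   chr02  = SHARED2
# where SHARED occurs in both cal01 and chr01.
crafted_pair <- function() {
  shared <- "ACGTACGGTTCAGCTTAGGC"           # 20 bp present in both genomes
  dupa   <- "TTGACCGTAA"                     # 10 bp duplicated in chr01
  filler <- function(seed, n) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
  cal01 <- paste0(filler(1, 30), shared, filler(2, 30))
  chr01 <- paste0(filler(3, 20), shared, filler(4, 15), dupa, filler(5, 15), dupa, filler(6, 10))
  chr02 <- filler(7, 80)
  structure(
    list(
      experimental = Biostrings::DNAStringSet(c(chr01 = chr01, chr02 = chr02)),
      calibration  = Biostrings::DNAStringSet(c(cal01 = cal01)),
      anchors      = c(chr01 = 55L, chr02 = 40L),
      read_length  = 10L
    ),
    class = "toy_genome_pair"
  )
}
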