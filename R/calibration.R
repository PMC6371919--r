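#' Compute the occupancy ratio from calibration counts
#'
#' The occupancy ratio (OR) is the spike-in calibration factor
#' \deqn{OR = \frac{W_c \times IP_x}{W_x \times IP_c}}
#' where `W_x`/`W_c` are WCE reads uniquely assigned to the experimental and
#' calibration genomes and `IP_x`/`IP_c` the same for the IP sample. Tracks
#' and profiles are made quantitatively comparable across samples by
#' multiplying by OR and normalizing to 1 million reads (see
#' [calibrate_profile()]). The OR is invariant under rescaling all four
#' counts by a common factor.
#'
#' @param counts a [calibration_counts()] object.
#' @param denominator which read total serves as the per-million denominator:
#'   `"experimental"` (default; uniquely assigned experimental-genome IP
#'   reads, `IP_x`) or `"all"` (all uniquely assigned IP reads,
#'   `IP_x + IP_c`).
#' @return A `calibration_result`: list with `OR` and
#'   `total_ip_experimental_reads` (the per-million denominator).
#' @examples
#' occupancy_ratio(calibration_counts(W_x = 100, W_c = 100, IP_x = 200, IP_c = 50))
#' @export
occupancy_ratio <- function(counts, denominator = c("experimental", "all")) {
  stopifnot(inherits(counts, "calibration_counts"))
  denominator <- match.arg(denominator)
  if (counts$W_x <= 0) stop("occupancy ratio undefined: W_x is zero")
  if (counts$IP_c <= 0) stop("occupancy ratio undefined: IP_c is zero")
  or <- (counts$W_c * counts$IP_x) / (counts$W_x * counts$IP_c)
  total <- switch(denominator,
    experimental = counts$IP_x,
    all = counts$IP_x + counts$IP_c
  )
  structure(
    list(OR = or, total_ip_experimental_reads = total),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Occupancy ratio:", format(x$OR, digits = 6),
      "| per-million denominator:", x$total_ip_experimental_reads, "reads\n")
  invisible(x)
}

#' Zero-filled per-base coverage pileup
#'
#' Computes read depth at every base of a chromosome, explicitly including
#' zero-coverage positions (the gap-filling step that makes per-base
#' averaging around anchors well defined). `depth[i]` is the number of reads
#' whose aligned interval covers base `i`; the sum of depths always equals
#' the summed aligned lengths of the contributing reads.
#'
#' @param assignments an `assigned_reads` data.frame; rows on other
#'   chromosomes or unassigned are ignored.
#' @param chrom chromosome name for the track.
#' @param length chromosome length in bp.
#' @return A `coverage_track`: list with `chrom`, `length`, `depth` (numeric
#'   vector indexed 1..length) and `state = "raw"`.
#' @export
zero_filled_pileup <- function(assignments, chrom, length) {
  stopifnot(is.data.frame(assignments), is_count(length))
  rows <- assignments$genome != "unassigned" & assignments$chrom == chrom
  rows[is.na(rows)] <- FALSE
  starts <- assignments$start[rows]
  ends <- starts + assignments$aligned_length[rows] - 1L
  if (any(starts < 1L) || any(ends > length)) {
    stop("read interval exceeds chromosome bounds on ", chrom)
  }
  diffs <- numeric(length + 1L)
  if (length(starts) > 0L) {
    add <- tabulate(starts, nbins = length)
    rem <- tabulate(ends + 1L, nbins = length + 1L)
    diffs[seq_len(length)] <- add
    diffs <- diffs - rem
  }
  depth <- cumsum(diffs[seq_len(length)])
  stopifnot(sum(depth) == sum(assignments$aligned_length[rows]))
  structure(
    list(chrom = chrom, length = as.integer(length), depth = depth, state = "raw"),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track", x$chrom, "(", x$length, "bp,", x$state, ")",
      "mean depth", format(mean(x$depth), digits = 4), "\n")
  invisible(x)
}

#' Anchor-centred meta-profile averaged across chromosomes
#'
#' For each offset d in \[-W, +W\] around the per-chromosome anchor (e.g. the
#' CDEIII element of each centromere), averages `depth[anchor + d]` over all
#' chromosomes whose coordinates cover that offset. Chromosomes whose window
#' is truncated by a chromosome end contribute only to in-bounds offsets;
#' `n_contributing` records the number of chromosomes entering each mean.
#'
#' @param tracks list of [zero_filled_pileup()] coverage tracks (one per
#'   chromosome), all in the same state.
#' @param anchors named vector of 1-based anchor positions, one per track
#'   chromosome.
#' @param W half-window in bp; the profile has exactly `2 * W + 1` offsets.
#'   The conventional window is 60000 (60 kb either side of the anchor).
#' @return A data.frame of class `meta_profile` with columns `offset`,
#'   `value` (mean depth; `NA` where no chromosome contributes) and
#'   `n_contributing`, and attributes `state` and `window`.
#' @export
anchor_meta_profile <- function(tracks, anchors, W = 60000) {
  if (!is.numeric(W) || length(W) != 1L || W < 0 || W != round(W)) {
    stop("W must be a non-negative integer number of bp")
  }
  stopifnot(is.list(tracks), length(tracks) > 0L)
  states <- unique(vapply(tracks, function(t) t$state, ""))
  if (length(states) != 1L) stop("all tracks must share the same state")
  W <- as.integer(W)
  offsets <- seq.int(-W, W)
  total <- numeric(length(offsets))
  n_contrib <- integer(length(offsets))
  for (tr in tracks) {
    stopifnot(inherits(tr, "coverage_track"))
    if (!tr$chrom %in% names(anchors)) {
      stop("anchor missing for chromosome ", tr$chrom)
    }
    a <- anchors[[tr$chrom]]
    in_bounds <- which(a + offsets >= 1L & a + offsets <= tr$length)
    total[in_bounds] <- total[in_bounds] + tr$depth[a + offsets[in_bounds]]
    n_contrib[in_bounds] <- n_contrib[in_bounds] + 1L
  }
  value <- ifelse(n_contrib > 0L, total / n_contrib, NA_real_)
  structure(
    data.frame(offset = offsets, value = value, n_contributing = n_contrib),
    class = c("meta_profile", "data.frame"),
    state = states, window = W
  )
}

#' Apply occupancy-ratio and per-million calibration
#'
#' Multiplies every value of a raw coverage track or meta-profile by
#' `OR * 1e6 / total_ip_experimental_reads`, turning raw depth into the
#' calibrated scale on which samples are quantitatively comparable.
#' Calibrating twice is an error: the scaling must be applied exactly once.
#'
#' @param profile a raw `coverage_track` or `meta_profile`.
#' @param calib a [occupancy_ratio()] `calibration_result`.
#' @return The same type of object with scaled values and state
#'   `"calibrated"`.
#' @export
calibrate_profile <- function(profile, calib) {
  stopifnot(inherits(calib, "calibration_result"))
  UseMethod("calibrate_profile")
}

#' @export
calibrate_profile.coverage_track <- function(profile, calib) {
  if (profile$state != "raw") stop("profile is already calibrated")
  profile$depth <- profile$depth * (calib$OR * 1e6 / calib$total_ip_experimental_reads)
  profile$state <- "calibrated"
  profile
}

#' @export
calibrate_profile.meta_profile <- function(profile, calib) {
  if (attr(profile, "state") != "raw") stop("profile is already calibrated")
  profile$value <- profile$value * (calib$OR * 1e6 / calib$total_ip_experimental_reads)
  attr(profile, "state") <- "calibrated"
  profile
}

#' Export a coverage track as a text genome-browser track
#'
#' Writes either a four-column bedGraph (0-based half-open intervals with
#' equal-value runs collapsed) or a `fixedStep start=1 step=1` wiggle.
#' Values are formatted at full double precision so that
#' [parse_track()] reproduces the depth vector exactly.
#'
#' @param track a `coverage_track`.
#' @param dialect `"bedGraph"` or `"wiggle"`.
#' @param file optional path; when given, lines are written there.
#' @return Character vector of track lines (invisibly when `file` is given).
#' @export
export_track <- function(track, dialect = c("bedGraph", "wiggle"), file = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  dialect <- match.arg(dialect)
  fmt <- function(v) sprintf("%.17g", v)
  lines <- if (dialect == "bedGraph") {
    r <- rle(track$depth)
    ends <- cumsum(r$lengths)
    starts0 <- c(0L, head(ends, -1L))
    sprintf("%s\t%d\t%d\t%s", track$chrom, starts0, ends, fmt(r$values))
  } else {
    c(sprintf("fixedStep chrom=%s start=1 step=1", track$chrom), fmt(track$depth))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Parse a bedGraph or wiggle text track back into a coverage track
#'
#' Inverse of [export_track()]; the dialect is detected from the content.
#'
#' @param lines character vector of track lines, or a file path of length 1
#'   pointing at an existing file.
#' @param state state to stamp on the resulting track (`"raw"` or
#'   `"calibrated"`).
#' @return A `coverage_track`.
#' @export
parse_track <- function(lines, state = "raw") {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  if (length(lines) == 0L) stop("empty track")
  if (startsWith(lines[[1L]], "fixedStep")) {
    chrom <- sub(".*chrom=(\\S+).*", "\\1", lines[[1L]])
    depth <- as.numeric(lines[-1L])
    len <- length(depth)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- parts[[1L]][1L]
    start0 <- vapply(parts, function(p) as.integer(p[2L]), 0L)
    end <- vapply(parts, function(p) as.integer(p[3L]), 0L)
    val <- vapply(parts, function(p) as.numeric(p[4L]), 0)
    len <- max(end)
    depth <- numeric(len)
    for (i in seq_along(val)) depth[(start0[i] + 1L):end[i]] <- val[i]
  }
  structure(
    list(chrom = chrom, length = as.integer(len), depth = depth, state = state),
    class = "coverage_track"
  )
}
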