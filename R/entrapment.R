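#' Interface names of the cohesin ring
#'
#' The three subunit interfaces that can carry engineered cysteine pairs:
#' the Smc1/Smc3 hinge, the Smc3/kleisin (Scc1 N-terminal) interface and the
#' kleisin/Smc1 (Scc1 C-terminal) interface. A "6C" copy carries cysteine
#' pairs at all three and can be covalently circularized by BMOE; a "5C"
#' copy lacks one pair and can never fully circularize.
#' @return Character vector of the three interface names.
#' @export
ring_interfaces <- function() c("hinge", "smc3_kleisin", "kleisin_smc1")

#' Build a ring stoichiometry model
#'
#' Describes a strain's cohesin pool for the minichromosome IP assay:
#' per-interface crosslink efficiencies, the copy composition (which copies
#' are fully circularizable and which carry the epitope tag used for IP),
#' the number `k` of kleisin-containing rings required per cohesive unit
#' (k = 1 is the ring model, k >= 2 the handcuff/oligomer model), and the
#' biological detection fractions `p_CM` (tagged complexes entrapping one
#' DNA) and `p_CD` (cohesive units on replicated minichromosomes).
#'
#' The default efficiencies of 0.6 per interface give a full-circularization
#' probability of 0.216, matching the observed 20--25% BMOE circularization
#' of 6C rings.
#'
#' @param copies list of copies, each a list with `interfaces` (character
#'   subset of [ring_interfaces()] carrying cysteine pairs) and `tagged`
#'   (logical). See [ring_copy()].
#' @param efficiencies named numeric vector of crosslink probabilities in
#'   \[0, 1\] for the three interfaces.
#' @param k rings per cohesive unit (>= 1).
#' @param p_CM,p_CD detection fractions in \[0, 1\].
#' @return A `stoichiometry_model` object.
#' @examples
#' m <- stoichiometry_model(copies = list(ring_copy(tagged = TRUE)))
#' circularization_fraction(m, 1)
#' @export
stoichiometry_model <- function(copies,
                                efficiencies = c(hinge = 0.6,
                                                 smc3_kleisin = 0.6,
                                                 kleisin_smc1 = 0.6),
                                k = 1L, p_CM = 0.3, p_CD = 0.3) {
  if (!is.list(copies) || length(copies) == 0L) stop("copies must be a non-empty list")
  stopifnot(setequal(names(efficiencies), ring_interfaces()))
  if (!all(vapply(efficiencies, is_fraction, TRUE))) {
    stop("interface efficiencies must lie in [0, 1]")
  }
  if (!is_count(k)) stop("k must be a positive integer")
  if (!is_fraction(p_CM) || !is_fraction(p_CD)) stop("p_CM and p_CD must lie in [0, 1]")
  for (cp in copies) {
    if (!is.list(cp) || !all(c("interfaces", "tagged") %in% names(cp))) {
      stop("each copy needs 'interfaces' and 'tagged'")
    }
    if (!all(cp$interfaces %in% ring_interfaces())) {
      stop("unknown interface in copy: ", paste(cp$interfaces, collapse = ", "))
    }
  }
  if (!any(vapply(copies, function(cp) isTRUE(cp$tagged), TRUE))) {
    stop("at least one copy must be tagged")
  }
  structure(
    list(efficiencies = efficiencies[ring_interfaces()], copies = copies,
         k = as.integer(k), p_CM = p_CM, p_CD = p_CD),
    class = "stoichiometry_model"
  )
}

#' Describe one expressed cohesin copy
#'
#' @param interfaces interfaces carrying cysteine pairs; the default (all
#'   three) is a 6C copy. A 5C copy omits one interface, conventionally the
#'   kleisin/Smc1 pair (the Scc1 A547C cysteine left out in 5C strains).
#' @param tagged whether this copy carries the IP epitope tag.
#' @return A list usable in [stoichiometry_model()]'s `copies`.
#' @export
ring_copy <- function(interfaces = ring_interfaces(), tagged = FALSE) {
  list(interfaces = interfaces, tagged = tagged)
}

#' Convenience constructor for the tetraploid test designs
#'
#' The two tetraploid strains used to discriminate ring from handcuff
#' cohesion: `"4x6C"` expresses four fully circularizable copies with a tag
#' on one of them; `"1x6C+3x5C"` expresses one tagged 6C copy and three 5C
#' copies that can never fully circularize.
#'
#' @param design `"4x6C"` or `"1x6C+3x5C"`.
#' @param ... passed to [stoichiometry_model()] (e.g. `k`, `efficiencies`).
#' @return A `stoichiometry_model`.
#' @export
tetraploid_design <- function(design = c("4x6C", "1x6C+3x5C"), ...) {
  design <- match.arg(design)
  five_c <- setdiff(ring_interfaces(), "kleisin_smc1")
  copies <- switch(design,
    "4x6C" = c(list(ring_copy(tagged = TRUE)),
               rep(list(ring_copy()), 3L)),
    "1x6C+3x5C" = c(list(ring_copy(tagged = TRUE)),
                    rep(list(ring_copy(interfaces = five_c)), 3L))
  )
  stoichiometry_model(copies = copies, ...)
}

#' @export
print.stoichiometry_model <- function(x, ...) {
  n6 <- sum(vapply(x$copies, function(cp) setequal(cp$interfaces, ring_interfaces()), TRUE))
  cat("Stoichiometry model:", length(x$copies), "copies (", n6, "fully circularizable ),",
      "k =", x$k, "\n  e =", paste(names(x$efficiencies), x$efficiencies,
                                   sep = "=", collapse = " "),
      " p_CM =", x$p_CM, " p_CD =", x$p_CD, "\n")
  invisible(x)
}

#' Full-circularization probability of one copy
#'
#' A copy circularizes only if all three interfaces carry cysteine pairs
#' (a 6C copy) and every interface crosslinks, which happens with probability
#' equal to the product of the per-interface efficiencies. A 5C copy returns
#' 0: it can never be covalently closed.
#'
#' @param model a [stoichiometry_model()].
#' @param copy_index index into `model$copies`.
#' @return Probability in \[0, 1\].
#' @export
circularization_fraction <- function(model, copy_index) {
  stopifnot(inherits(model, "stoichiometry_model"))
  if (!is_count(copy_index) || copy_index > length(model$copies)) {
    stop("copy_index out of range")
  }
  cp <- model$copies[[copy_index]]
  if (!setequal(cp$interfaces, ring_interfaces())) return(0)
  prod(model$efficiencies[cp$interfaces])
}

#' Expected detectable CM and CD fractions
#'
#' Closed form for the fractions of catenated monomers (CM) and catenated
#' dimers (CD) detectable in the minichromosome IP under the model.
#' A CM requires the tagged copy to be fully circularized:
#' `CM = p_CM * mean(c_tagged)`. A CD requires every ring of a k-ring
#' cohesive unit to be circularized; partner rings are drawn uniformly with
#' replacement from the expressed pool, and the IP conditions on the tagged
#' copy being a member, so `CD = p_CD * c_tagged * m^(k-1)` with `m` the
#' mean circularization fraction over all copies (averaged over tagged
#' copies when several are tagged).
#'
#' @param model a [stoichiometry_model()].
#' @return Named list with `CM_detectable` and `CD_detectable`.
#' @export
expected_species_fractions <- function(model) {
  stopifnot(inherits(model, "stoichiometry_model"))
  circ <- vapply(seq_along(model$copies),
                 function(i) circularization_fraction(model, i), 0)
  tagged <- vapply(model$copies, function(cp) isTRUE(cp$tagged), TRUE)
  m <- mean(circ)
  cm <- model$p_CM * mean(circ[tagged])
  cd <- model$p_CD * mean(circ[tagged] * m^(model$k - 1L))
  list(CM_detectable = cm, CD_detectable = cd)
}

#' Ratio of CD/CM ratios between two designs
#'
#' The diagnostic statistic of the ring-vs-handcuff test: the CD/CM ratio of
#' a control design divided by that of a test design, computed from
#' [expected_species_fractions()]. Under the ring model (k = 1) the
#' statistic equals 1 for any copy composition and efficiencies; under a
#' k-ring handcuff model with the 4x6C vs 1x6C+3x5C tetraploid pair it
#' equals `4^(k-1)` (so 4 for k = 2, the reciprocal of the predicted
#' one-quarter CD fraction).
#'
#' @param design_control,design_test two [stoichiometry_model()]s.
#' @return Dimensionless ratio.
#' @export
ratio_of_ratios <- function(design_control, design_test) {
  fc <- expected_species_fractions(design_control)
  ft <- expected_species_fractions(design_test)
  if (fc$CM_detectable <= 0) stop("ratio undefined: control CM fraction is zero")
  if (ft$CM_detectable <= 0 || ft$CD_detectable <= 0) {
    stop("ratio undefined: test CM or CD fraction is zero")
  }
  (fc$CD_detectable / fc$CM_detectable) / (ft$CD_detectable / ft$CM_detectable)
}

#' Quantify a gel lane as percentages of total intensity
#'
#' Converts band intensities to the percentage-of-lane scale used for
#' Southern blot densitometry: each band's intensity as a percentage of the
#' total pixel intensity of the lane. Band order is preserved.
#'
#' @param bands named, ordered numeric vector of band intensities
#'   (arbitrary units, >= 0, not all zero).
#' @return A `lane_quant` object: list with `bands` and `percent`.
#' @examples
#' quantify_lane(c(monomer = 50, CM = 25, CD = 25))$percent
#' @export
quantify_lane <- function(bands) {
  stopifnot(is.numeric(bands), length(bands) > 0L, !is.null(names(bands)))
  if (any(bands < 0)) stop("band intensities must be non-negative")
  total <- sum(bands)
  if (total <= 0) stop("empty lane: total intensity is zero")
  structure(
    list(bands = bands, percent = 100 * bands / total),
    class = "lane_quant"
  )
}

#' @export
print.lane_quant <- function(x, ...) {
  cat("Lane:", paste(sprintf("%s=%.3g%%", names(x$percent), x$percent),
                     collapse = " "), "\n")
  invisible(x)
}

#' Mean and SD of band percentages across replicate lanes
#'
#' @param lanes list of [quantify_lane()] objects with identical band labels.
#' @return A data.frame of class `replicate_summary` with columns `band`,
#'   `mean`, `sd` (sample SD, n-1 denominator; `NA` for a single lane) and
#'   `n`.
#' @export
replicate_stats <- function(lanes) {
  stopifnot(is.list(lanes), length(lanes) >= 1L)
  labels <- names(lanes[[1L]]$percent)
  for (ln in lanes) {
    stopifnot(inherits(ln, "lane_quant"))
    if (!identical(names(ln$percent), labels)) {
      stop("mismatched band labels across lanes: ",
           paste(union(setdiff(names(ln$percent), labels),
                       setdiff(labels, names(ln$percent))), collapse = ", "))
    }
  }
  mat <- do.call(rbind, lapply(lanes, function(ln) ln$percent))
  n <- nrow(mat)
  structure(
    data.frame(
      band = labels,
      mean = colMeans(mat),
      sd = if (n > 1L) apply(mat, 2L, sd) else NA_real_,
      n = n,
      row.names = NULL
    ),
    class = c("replicate_summary", "data.frame")
  )
}

#' Classify the kleisin stoichiometry from an observed ratio of ratios
#'
#' Formalizes the verbal inference of the tetraploid experiment: given the
#' observed control/test CD-to-CM ratio of ratios and its SD, compute a
#' z-score against the prediction for each candidate k
#' (via [ratio_of_ratios()] on the supplied designs) and pick the candidate
#' with the smallest z. Ties are broken toward the smaller k (parsimony) and
#' flagged.
#'
#' @param observed_ratio_of_ratios observed statistic.
#' @param observed_sd its standard deviation (> 0).
#' @param candidate_k integer vector of candidate ring counts.
#' @param design_control,design_test design pair used for the predictions;
#'   defaults to the tetraploid 4x6C vs 1x6C+3x5C pair.
#' @return List with `best_k`, `z_per_k` (named numeric) and `tie` (logical).
#' @examples
#' classify_stoichiometry(1.01, 0.100, c(1, 2))
#' @export
classify_stoichiometry <- function(observed_ratio_of_ratios, observed_sd,
                                   candidate_k,
                                   design_control = tetraploid_design("4x6C"),
                                   design_test = tetraploid_design("1x6C+3x5C")) {
  if (length(candidate_k) == 0L) stop("candidate_k must be non-empty")
  stopifnot(is.numeric(observed_sd), observed_sd > 0)
  candidate_k <- sort(unique(as.integer(candidate_k)))
  z <- vapply(candidate_k, function(k) {
    ctrl <- design_control; ctrl$k <- k
    test <- design_test; test$k <- k
    pred <- ratio_of_ratios(ctrl, test)
    abs(observed_ratio_of_ratios - pred) / observed_sd
  }, 0)
  names(z) <- candidate_k
  best <- which(z == min(z))
  list(
    best_k = candidate_k[best[1L]],   # smallest k on ties (candidates sorted)
    z_per_k = z,
    tie = length(best) > 1L
  )
}

#' Observed CD/CM ratio of one lane
#'
#' @param lane a [quantify_lane()] result containing `CM` and `CD` bands.
#' @return `CD / CM` band-intensity ratio.
#' @export
cd_cm_ratio <- function(lane) {
  stopifnot(inherits(lane, "lane_quant"),
            all(c("CM", "CD") %in% names(lane$bands)))
  unname(lane$bands[["CD"]] / lane$bands[["CM"]])
}
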