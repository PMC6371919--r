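#' Simulate replicate gel lanes of the minichromosome IP assay
#'
#' Generates lane quantifications under a chosen ring stoichiometry model.
#' Each replicate's CM and CD band intensities equal 100 times the model's
#' expected detectable fractions (from [expected_species_fractions()])
#' multiplied by independent log-normal noise with multiplicative SD
#' `noise_sd`; the monomer and concatemer background bands are included at
#' fixed nominal levels. With `noise_sd = 0` every replicate equals the
#' model expectation exactly.
#'
#' @param model a [stoichiometry_model()].
#' @param n_replicates number of lanes (biological replicates).
#' @param noise_sd multiplicative gel noise SD, in \[0, 1).
#' @param seed integer RNG seed.
#' @param monomer_level,concatemer_level nominal intensities of the
#'   background bands (arbitrary units).
#' @return List of `n_replicates` [quantify_lane()] objects with bands
#'   `monomer`, `concatemer`, `CM`, `CD`.
#' @examples
#' m <- tetraploid_design("4x6C", k = 1)
#' lanes <- simulate_entrapment_assay(m, n_replicates = 3, noise_sd = 0.1, seed = 1)
#' replicate_stats(lanes)
#' @export
simulate_entrapment_assay <- function(model, n_replicates, noise_sd, seed,
                                      monomer_level = 50, concatemer_level = 5) {
  stopifnot(inherits(model, "stoichiometry_model"))
  if (!is_count(n_replicates)) stop("n_replicates must be a positive integer")
  if (!is.numeric(noise_sd) || noise_sd < 0 || noise_sd >= 1) {
    stop("noise_sd must lie in [0, 1)")
  }
  fr <- expected_species_fractions(model)
  cm0 <- 100 * fr$CM_detectable
  cd0 <- 100 * fr$CD_detectable
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      noise <- exp(rnorm(2L, mean = 0, sd = noise_sd))
      quantify_lane(c(
        monomer = monomer_level,
        concatemer = concatemer_level,
        CM = cm0 * noise[1L],
        CD = cd0 * noise[2L]
      ))
    })
  })
}

#' Simulate a phosphate-release absorbance series
#'
#' Emulates the coupled phosphate-detection readout of an ATPase assay:
#' absorbance at 360 nm sampled every `interval` minutes rises linearly at
#' `true_rate * curve$slope` AU/min until `saturation_time`, then stays
#' constant, with additive Gaussian noise. The 90 min duration and 0.5 min
#' interval defaults match reading the plate every 30 s for 90 min.
#'
#' @param true_rate phosphate release rate in uM/min.
#' @param duration total time in minutes.
#' @param interval sampling interval in minutes (> 0).
#' @param curve a [standard_curve()] mapping uM phosphate to AU.
#' @param saturation_time minutes after which the signal plateaus
#'   (0 <= saturation_time <= duration; default no plateau).
#' @param noise_sd additive Gaussian noise SD in AU.
#' @param seed integer RNG seed.
#' @return An `absorbance_series` data.frame with columns `time` (min) and
#'   `au`.
#' @examples
#' cv <- standard_curve(slope = 0.01, intercept = 0.1)
#' s <- simulate_atpase_series(2, curve = cv, noise_sd = 0, seed = 1)
#' atpase_rate(s, cv)$rate
#' @export
simulate_atpase_series <- function(true_rate, duration = 90, interval = 0.5,
                                   curve = standard_curve(slope = 0.01, intercept = 0.1),
                                   saturation_time = duration, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(is.numeric(true_rate), length(true_rate) == 1L)
  stopifnot(is.numeric(interval), interval > 0)
  stopifnot(is.numeric(duration), duration > 0)
  if (!is.numeric(saturation_time) || saturation_time < 0 || saturation_time > duration) {
    stop("saturation_time must satisfy 0 <= saturation_time <= duration")
  }
  stopifnot(inherits(curve, "standard_curve"), is.numeric(noise_sd), noise_sd >= 0)
  times <- seq(0, duration, by = interval)
  au <- curve$intercept + curve$slope * true_rate * pmin(times, saturation_time)
  au <- with_seed(seed, au + rnorm(length(times), mean = 0, sd = noise_sd))
  structure(
    data.frame(time = times, au = au),
    class = c("absorbance_series", "data.frame")
  )
}
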