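#' Replicate noise model for synthetic tracer measurements
#'
#' Gaussian noise applied to individual replicate values around the
#' noise-free model prediction, with standard deviation
#' `max(cv * mean, sd_floor)` and truncation of negative draws at zero
#' (scintillation counts cannot be negative). Noise is drawn per
#' replicate, not per mean, so the reported per-point standard deviations
#' are themselves realistic random variables.
#'
#' @param cv coefficient of variation (unitless; SD = cv * mean).
#' @param sd_floor absolute SD floor, pmol per 1e6 cells; keeps points
#'   with a zero prediction (e.g. t = 0) from having exactly zero spread.
#' @return An object of class `tim2_noise`.
#' @export
noise_model <- function(cv = 0.10, sd_floor = 0) {
  if (cv < 0 || sd_floor < 0)
    stop("cv and sd_floor must be >= 0", call. = FALSE)
  structure(list(cv = cv, sd_floor = sd_floor), class = "tim2_noise")
}

#' Generate a synthetic timecourse dataset
#'
#' Simulates the noise-free observables of a protocol, draws `n_reps`
#' Gaussian replicates per point under the noise model, and summarises
#' them to the (mean, SD, n) records the SSNE objective consumes —
#' emulating the triplicate 55Fe measurements of the laboratory
#' protocols. Deterministic given `seed`.
#'
#' @param params a `tim2_parameters` object.
#' @param protocol a `tim2_protocol`.
#' @param noise a `tim2_noise` object.
#' @param n_reps replicates per point (>= 1).
#' @param seed integer seed.
#' @param observables observable ids to include; defaults to the
#'   protocol's standard observables.
#' @return A `tim2_dataset`: a data frame with columns `experiment`,
#'   `observable`, `time_min`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' d <- generate_dataset(table1_parameters(),
#'                       build_protocol("uptake", "tim2"), seed = 1)
#' head(d)
generate_dataset <- function(params, protocol, noise = noise_model(),
                             n_reps = 3, seed = 1,
                             observables = protocol$observables) {
  stopifnot(inherits(noise, "tim2_noise"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  traj <- simulate_protocol(protocol, params)
  set.seed(as.integer(seed))
  recs <- lapply(observables, function(obs) {
    tc <- observe(traj, obs)
    sds <- pmax(noise$cv * tc$value, noise$sd_floor)
    reps <- matrix(stats::rnorm(nrow(tc) * n_reps, mean = tc$value,
                                sd = sds),
                   nrow = nrow(tc))
    reps[reps < 0] <- 0
    data.frame(experiment = protocol$experiment,
               observable = obs,
               time_min = tc$time_min,
               mean = rowMeans(reps),
               sd = if (n_reps > 1) apply(reps, 1, stats::sd) else 0,
               n = n_reps)
  })
  ds <- do.call(rbind, recs)
  rownames(ds) <- NULL
  class(ds) <- c("tim2_dataset", "data.frame")
  ds
}

#' Standard synthetic fixture suite
#'
#' The three-experiment dataset collection that stands in for the
#' laboratory measurements: uptake in TIM-2 and vector cells (total
#' cell-associated label on the 0-120 min grid), pulse-chase storage in
#' TIM-2 cells (biotinylated and non-biotinylated fractions on the 0-48 h
#' post-wash grid), and export in TIM-2 and vector cells (media label on
#' the 0-48 h grid), generated at the given parameters with triplicate
#' Gaussian noise.
#'
#' @param seed integer seed.
#' @param params generating parameters; defaults to the packaged
#'   reference set.
#' @param cv,sd_floor noise settings (see [noise_model()]).
#' @param n_reps replicates per point.
#' @return A named list of three `tim2_dataset` objects: `uptake`,
#'   `storage`, `export`.
#' @export
fixture_suite <- function(seed = 1, params = table1_parameters(),
                          cv = 0.10, sd_floor = 0, n_reps = 3) {
  nm <- noise_model(cv = cv, sd_floor = sd_floor)
  seed <- as.integer(seed)
  list(
    uptake = as_timecourse_dataset(rbind(
      generate_dataset(params, build_protocol("uptake", "tim2"), nm,
                       n_reps, seed = seed),
      generate_dataset(params, build_protocol("uptake", "vector"), nm,
                       n_reps, seed = seed + 1L))),
    storage = generate_dataset(params, build_protocol("storage", "tim2"),
                               nm, n_reps, seed = seed + 2L),
    export = as_timecourse_dataset(rbind(
      generate_dataset(params, build_protocol("export", "tim2"), nm,
                       n_reps, seed = seed + 3L),
      generate_dataset(params, build_protocol("export", "vector"), nm,
                       n_reps, seed = seed + 4L))))
}
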