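#' Observable identifiers
#'
#' The measurable tracer signals, each the sum of the iron-containing
#' model pools it aggregates: `cell_total_55fe = x1 + x4 + x7 + x9` (all
#' cell-associated label, as counted after PBS washes), `biotinylated_55fe
#' = x7 + x9` (label still carried by intact exogenous, biotin-tagged
#' HFt), `nonbiotinylated_55fe = x1 + x4` (label released from exogenous
#' HFt into the LIP or endogenous ferritin), and `media_55fe =
#' media_exported` (cumulative exported label).
#'
#' @format A character vector of the four observable ids.
#' @export
observable_ids <- c("cell_total_55fe", "biotinylated_55fe",
                    "nonbiotinylated_55fe", "media_55fe")

.observable_pools <- list(
  cell_total_55fe      = c("x1", "x4", "x7", "x9"),
  biotinylated_55fe    = c("x7", "x9"),
  nonbiotinylated_55fe = c("x1", "x4"),
  media_55fe           = "media_exported"
)

# Default observables reported by each experiment.
.default_observables <- list(
  uptake  = "cell_total_55fe",
  storage = c("biotinylated_55fe", "nonbiotinylated_55fe"),
  export  = "media_55fe"
)

.phase <- function(duration_min, media_reset = c("none", "set", "wash"),
                   media_value = NA_real_, ferritin_media = FALSE,
                   notes = "") {
  media_reset <- match.arg(media_reset)
  if (duration_min < 0) stop("phase duration must be >= 0", call. = FALSE)
  list(duration_min = duration_min, media_reset = media_reset,
       media_value = media_value, ferritin_media = ferritin_media,
       notes = notes)
}

#' Build one of the three tracer experiment protocols
#'
#' Encodes an experiment as an ordered list of phases (exposure, wash,
#' chase) with a sampling grid and an initial-condition recipe:
#'
#' * `uptake`: a single 120-min exposure to labelled Fe-HFt, sampled at
#'   0, 5, 15, 30, 60, 90 and 120 min; measured signal is total
#'   cell-associated label.
#' * `storage`: a 2-h exposure to biotinylated labelled Fe-HFt, a PBS wash
#'   (media label zeroed; surface-bound complexes retained), then a 48-h
#'   chase sampled at 0, 2, 4, 8, 24 and 48 h post-wash; measured signals
#'   are the biotinylated and non-biotinylated cell fractions.
#' * `export`: cells preloaded with labelled iron through transferrin
#'   (default 10.8 pmol per 1e6 cells, partitioned by [equilibrate()]),
#'   chased in media initially carrying 2.4 pmol per 1e6 cells of
#'   non-ferritin label, sampled at 0, 2, 4, 24 and 48 h; measured signal
#'   is cumulative exported label. The apo-HFt treatment of the
#'   laboratory protocol carries no labelled iron and is modelled as
#'   having no effect on labelled flux.
#'
#' Time is handled in minutes internally; the hour-denominated grids of
#' the storage and export experiments are converted at this interface.
#'
#' @param name one of `"uptake"`, `"storage"`, `"export"`.
#' @param cell_line `"tim2"` or `"vector"` (empty-vector control, zero
#'   membrane TIM-2 capacity).
#' @param media_label media tracer level during ferritin exposure, pmol
#'   per 1e6 cells; the default (100) puts the media in large excess of
#'   cellular uptake.
#' @param preload_cell cell tracer preload for the export experiment.
#' @param export_media_label initial media tracer for the export chase.
#' @param x6_override optional membrane TIM-2 capacity overriding
#'   `params$x6_total` at simulation time.
#' @return An object of class `tim2_protocol`.
#' @export
#' @examples
#' build_protocol("storage", "tim2")
build_protocol <- function(name = c("uptake", "storage", "export"),
                           cell_line = c("tim2", "vector"),
                           media_label = 100,
                           preload_cell = 10.8,
                           export_media_label = 2.4,
                           x6_override = NULL) {
  name <- match.arg(name)
  cell_line <- match.arg(cell_line)
  pr <- switch(
    name,
    uptake = list(
      phases = list(.phase(120, "set", media_label, ferritin_media = TRUE,
                           notes = "55Fe-HFt exposure")),
      sample_times_min = c(0, 5, 15, 30, 60, 90, 120),
      time_offset_min = 0,
      preload_cell = 0),
    storage = list(
      phases = list(
        .phase(120, "set", media_label, ferritin_media = TRUE,
               notes = "biotin-55Fe-HFt exposure"),
        .phase(2880, "wash", notes = "PBS wash, chase in growth media")),
      sample_times_min = 120 + c(0, 2, 4, 8, 24, 48) * 60,
      time_offset_min = 120,
      preload_cell = 0),
    export = list(
      phases = list(.phase(2880, "set", export_media_label,
                           ferritin_media = FALSE,
                           notes = "chase after Tf-55Fe preload")),
      sample_times_min = c(0, 2, 4, 24, 48) * 60,
      time_offset_min = 0,
      preload_cell = preload_cell))
  pr$name <- name
  pr$cell_line <- cell_line
  pr$x6_override <- x6_override
  pr$observables <- .default_observables[[name]]
  pr$experiment <- paste(name, cell_line, sep = "_")
  class(pr) <- "tim2_protocol"
  pr
}

#' @export
print.tim2_protocol <- function(x, ...) {
  cat("Protocol:", x$name, "(", x$cell_line, "cells )\n")
  for (i in seq_along(x$phases)) {
    ph <- x$phases[[i]]
    cat(sprintf("  phase %d: %g min, media %s%s, %s\n", i, ph$duration_min,
                ph$media_reset,
                if (ph$media_reset == "set") paste0(" -> ", ph$media_value) else "",
                ph$notes))
  }
  cat("  sampling (min, reported):",
      paste(x$sample_times_min - x$time_offset_min, collapse = " "), "\n")
  invisible(x)
}

#' Simulate a protocol
#'
#' Integrates the tracer model phase by phase with [deSolve::lsoda()],
#' applying media resets at phase boundaries (a wash zeroes unbound media
#' label and leaves all cell-associated pools, including surface-bound
#' complexes, untouched) and restarting the integrator at each boundary.
#' The receptor binding coefficient within a phase is referenced to the
#' media label at that phase's start, so media depletion slows binding.
#'
#' @param protocol a `tim2_protocol`.
#' @param params a `tim2_parameters` object.
#' @param times optional reported-time sampling grid (minutes, relative to
#'   the protocol's reporting origin) replacing the protocol's default
#'   grid.
#' @param rtol,atol integrator tolerances.
#' @param compiled integrate with the compiled right-hand side (default)
#'   or the reference R implementation [iron_rhs()].
#' @param literal_hill passed to the right-hand side; see [iron_rhs()].
#' @param initial_state optional full state vector replacing the
#'   [equilibrate()]-derived initial condition (media resets of the first
#'   phase still apply).
#' @return A `tim2_trajectory`: a data frame with columns `time_min`
#'   (reported time) plus the eleven state variables, one row per
#'   snapshot.
#' @export
#' @examples
#' tr <- simulate_protocol(build_protocol("uptake", "tim2"),
#'                         table1_parameters())
#' observe(tr, "cell_total_55fe")
simulate_protocol <- function(protocol, params, times = NULL,
                              rtol = 1e-8, atol = 1e-10, compiled = TRUE,
                              literal_hill = FALSE, initial_state = NULL) {
  stopifnot(inherits(protocol, "tim2_protocol"))
  validate_parameters(params)
  if (!is.null(protocol$x6_override)) {
    params$x6_total <- protocol$x6_override
    validate_parameters(params)
  }

  sample_global <- if (is.null(times)) protocol$sample_times_min else {
    if (any(times < 0)) stop("sampling times must be >= 0", call. = FALSE)
    sort(unique(times)) + protocol$time_offset_min
  }
  total_dur <- sum(vapply(protocol$phases, `[[`, 0, "duration_min"))
  if (any(sample_global > total_dur + 1e-9))
    stop("sampling times fall outside the protocol phases", call. = FALSE)

  first_media <- protocol$phases[[1]]
  if (is.null(initial_state)) {
    y <- equilibrate(params, cell_line = protocol$cell_line,
                     preload_cell = protocol$preload_cell,
                     media_label = if (first_media$media_reset == "set")
                       first_media$media_value else 0)
  } else {
    y <- .check_state(initial_state)
    names(y) <- .state_names
  }

  tim2_present <- protocol$cell_line == "tim2"
  out <- NULL
  t0 <- 0
  for (ph in protocol$phases) {
    if (ph$media_reset == "wash") y[["media_unbound"]] <- 0
    else if (ph$media_reset == "set") y[["media_unbound"]] <- ph$media_value
    t1 <- t0 + ph$duration_min
    tt <- sort(unique(c(t0, sample_global[sample_global >= t0 - 1e-9 &
                                            sample_global <= t1 + 1e-9], t1)))
    if (ph$duration_min > 0) {
      sol <- .integrate_phase(y, tt, params, tim2_present,
                              media_ref = y[["media_unbound"]],
                              ferritin_media = ph$ferritin_media,
                              literal_hill = literal_hill,
                              rtol = rtol, atol = atol, compiled = compiled)
    } else {
      sol <- matrix(c(t0, y), nrow = 1,
                    dimnames = list(NULL, c("time", .state_names)))
    }
    keep <- vapply(sol[, 1], function(t)
      any(abs(t - sample_global) < 1e-9), TRUE)
    out <- rbind(out, sol[keep, , drop = FALSE])
    y <- sol[nrow(sol), -1]
    names(y) <- .state_names
    # integrator round-off can leave pools marginally negative
    y[y < 0 & y > -atol * 100] <- 0
    .check_state(y, tol = atol * 100)
    t0 <- t1
  }
  # at a phase boundary keep the post-reset snapshot (e.g. media zeroed by
  # the wash), not the pre-reset one
  out <- out[!duplicated(out[, 1], fromLast = TRUE), , drop = FALSE]
  traj <- as.data.frame(out)
  names(traj) <- c("time_min", .state_names)
  traj$time_min <- traj$time_min - protocol$time_offset_min
  traj <- traj[traj$time_min >= -1e-9, , drop = FALSE]
  rownames(traj) <- NULL
  if (is.unsorted(traj$time_min, strictly = TRUE))
    stop("simulation error: snapshot times not strictly increasing",
         call. = FALSE)
  attr(traj, "protocol") <- protocol
  class(traj) <- c("tim2_trajectory", "data.frame")
  traj
}

.integrate_phase <- function(y, tt, params, tim2_present, media_ref,
                             ferritin_media, literal_hill, rtol, atol,
                             compiled) {
  if (compiled) {
    pv <- .pack_parms(params, tim2_present = tim2_present,
                      media_ref = media_ref,
                      ferritin_media = ferritin_media,
                      literal_hill = literal_hill)
    sol <- deSolve::lsoda(y, tt, func = "tim2_derivs", parms = pv,
                          dllname = "tim2iron", initfunc = "tim2_initmod",
                          rtol = rtol, atol = atol)
  } else {
    sol <- deSolve::lsoda(y, tt, func = function(t, yy, pp) {
      names(yy) <- .state_names
      iron_rhs(t, yy, pp, tim2_present = tim2_present,
               media_ref = media_ref, ferritin_media = ferritin_media,
               literal_hill = literal_hill)
    }, parms = params, rtol = rtol, atol = atol)
  }
  di <- attr(sol, "istate")
  if (!is.null(di) && di[1] < 0)
    stop("simulation error: integrator failed (istate ", di[1],
         ") in phase starting at t = ", tt[1], " min", call. = FALSE)
  unclass(sol)
}

#' Extract an observable timecourse from a trajectory
#'
#' @param trajectory a `tim2_trajectory`.
#' @param observable one of [observable_ids].
#' @return A data frame with columns `time_min` (reported time) and
#'   `value` (pmol per 1e6 cells).
#' @export
observe <- function(trajectory, observable) {
  stopifnot(inherits(trajectory, "tim2_trajectory"))
  if (length(observable) != 1L || !observable %in% observable_ids)
    stop("unknown observable: ", paste(observable, collapse = ", "),
         call. = FALSE)
  pools <- .observable_pools[[observable]]
  value <- rowSums(trajectory[, pools, drop = FALSE])
  data.frame(time_min = trajectory$time_min, value = pmax(value, 0))
}

#' Log-linear decay rate of a timecourse window
#'
#' Fits a least-squares line to `log(value)` against time over the given
#' window and returns the negated slope: the effective first-order decay
#' rate of the signal in that window. Used to read off the slow
#' (second-phase) degradation constant of biotinylated ferritin from the
#' late chase of the storage experiment.
#'
#' @param timecourse a data frame with columns `time_min` and `value`.
#' @param window numeric length-2 time interval (min, inclusive).
#' @return Decay rate, per min.
#' @export
#' @examples
#' tc <- data.frame(time_min = 0:10 * 100, value = exp(-0.00031 * 0:10 * 100))
#' phase_two_decay_rate(tc, c(0, 1000))
phase_two_decay_rate <- function(timecourse, window) {
  stopifnot(is.data.frame(timecourse),
            all(c("time_min", "value") %in% names(timecourse)),
            length(window) == 2)
  sel <- timecourse$time_min >= min(window) & timecourse$time_min <= max(window)
  tc <- timecourse[sel, , drop = FALSE]
  if (nrow(tc) < 3)
    stop("need at least 3 points in the window (got ", nrow(tc), ")",
         call. = FALSE)
  if (any(tc$value <= 0))
    stop("domain error: non-positive values in the window; cannot take logs",
         call. = FALSE)
  fit <- stats::lm(log(value) ~ time_min, data = tc)
  -unname(stats::coef(fit)[2])
}
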