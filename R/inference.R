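#' Sum of squares due to normalised error (SSNE)
#'
#' The co-fitting objective: `sum_j (m_j - y_j)^2 / sigma_j^2` over all
#' data points of all included experiments, where `m_j` is the model
#' prediction, `y_j` the measured mean and `sigma_j` its replicate
#' standard deviation. Points with a zero (or unreported) SD are given a
#' floor of `sd_floor_frac` times the largest absolute mean in the
#' dataset, so the objective stays finite for noise-free data.
#'
#' @param predictions numeric vector of model values `m_j`, aligned
#'   row-for-row with `data`.
#' @param data a `tim2_dataset`.
#' @param sd_floor_frac relative SD floor (see Description).
#' @return A non-negative scalar.
#' @export
#' @examples
#' d <- data.frame(experiment = "x", observable = "cell_total_55fe",
#'                 time_min = 0, mean = 1, sd = 2, n = 3)
#' ssne(3, as_timecourse_dataset(d))   # (3-1)^2 / 2^2 = 1
ssne <- function(predictions, data, sd_floor_frac = 0.001) {
  r <- .ssne_residuals(predictions, data, sd_floor_frac)
  sum(r^2)
}

.ssne_residuals <- function(predictions, data, sd_floor_frac = 0.001) {
  stopifnot(inherits(data, "tim2_dataset"))
  if (length(predictions) != nrow(data) || anyNA(predictions))
    stop("alignment error: need one finite prediction per data point",
         call. = FALSE)
  sigma <- pmax(data$sd, sd_floor_frac * max(abs(data$mean)))
  (predictions - data$mean) / sigma
}

#' Model predictions aligned to a dataset
#'
#' Simulates each experiment present in the dataset with its protocol and
#' reads off the observables at the measured times, returning the
#' prediction vector `m` in data-row order.
#'
#' @param params a `tim2_parameters` object.
#' @param protocols a named list of `tim2_protocol` objects; names must
#'   cover the dataset's `experiment` values.
#' @param data a `tim2_dataset`.
#' @return Numeric vector of length `nrow(data)`.
#' @export
predict_dataset <- function(params, protocols, data) {
  stopifnot(inherits(data, "tim2_dataset"))
  m <- rep(NA_real_, nrow(data))
  for (ex in unique(data$experiment)) {
    pr <- protocols[[ex]]
    if (is.null(pr))
      stop("alignment error: no protocol supplied for experiment '", ex,
           "'", call. = FALSE)
    rows_ex <- which(data$experiment == ex)
    traj <- simulate_protocol(pr, params,
                              times = unique(data$time_min[rows_ex]))
    for (obs in unique(data$observable[rows_ex])) {
      tc <- observe(traj, obs)
      rows <- rows_ex[data$observable[rows_ex] == obs]
      idx <- match(round(data$time_min[rows], 6), round(tc$time_min, 6))
      if (anyNA(idx))
        stop("alignment error: unmatched sampling time for '", ex, "' / ",
             obs, call. = FALSE)
      m[rows] <- tc$value[idx]
    }
  }
  m
}

#' Default free-parameter set for co-fitting
#'
#' The controlling parameters of the TIM-2 pathway that the tracer
#' experiments inform, plus the initial membrane-capacity nuisance
#' parameter: combination coefficient, endosome formation rate, recycling
#' rate, surviving fraction, slow degradation rate, saturation threshold,
#' direct-uptake coefficient, export coefficient, and total TIM-2
#' capacity. Core-model constants stay fixed under the frozen-core
#' (linear-regime) default.
#'
#' @return Character vector of parameter names.
#' @export
default_free_params <- function() {
  c("alpha7_Ftex", "gamma7", "gamma6", "alpha9", "gamma9", "K47",
    "alpha1_Feex_x2", "alpha6_x3_eff", "x6_total")
}

.default_bounds <- function(free, base, span = 10) {
  lower <- upper <- numeric(length(free))
  names(lower) <- names(upper) <- free
  for (nm in free) {
    v <- base[[nm]]
    if (is.null(v) || v <= 0)
      stop("cannot derive bounds for parameter '", nm, "'", call. = FALSE)
    lower[nm] <- v / span
    upper[nm] <- v * span
  }
  for (nm in intersect(free, c("alpha9", "alpha10", "alpha11")))
    upper[nm] <- min(upper[nm], 1)
  list(lower = lower, upper = upper)
}

#' Co-fit model parameters to timecourse datasets by SSNE minimisation
#'
#' Minimises the [ssne()] objective over the chosen free parameters,
#' shared jointly across all supplied experiments. Parameters are
#' log-scaled (they are positive rates spanning decades) and optimised
#' under box bounds by Levenberg-Marquardt on the normalised residuals
#' ([minpack.lm::nls.lm]), restarted from `n_starts` Latin-hypercube
#' draws over the log-bound box. Deterministic given `seed`.
#'
#' After the best start converges, each free parameter is perturbed at
#' the optimum; a parameter whose perturbation leaves the objective
#' numerically unchanged is flagged as unidentifiable (e.g. TIM-2
#' parameters fitted against vector-cell data only).
#'
#' @param data a `tim2_dataset`, or a list of them (rows are pooled; the
#'   objective is additive over points).
#' @param protocols named list of `tim2_protocol` objects keyed by the
#'   dataset's `experiment` labels.
#' @param free character vector of free parameter names (fields of
#'   [model_parameters()]).
#' @param base_params fixed values for the non-free parameters, and the
#'   centre used for default bounds.
#' @param lower,upper optional named bound vectors on the natural scale;
#'   default is `base_params` divided/multiplied by `bound_span` (with
#'   fractions capped at 1).
#' @param bound_span span factor for the default bounds.
#' @param n_starts number of Latin-hypercube starts.
#' @param seed integer seed for the start design.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param ssne_tol objective tolerance for convergence.
#' @param sd_floor_frac relative SD floor passed to the objective.
#' @return A `tim2_fit` object: list with `estimates` (named vector),
#'   `ssne`, `per_start` (per-start objective trace), `converged`,
#'   `unidentifiable` (names of flat parameters, possibly empty), `seed`,
#'   `free`, `lower`, `upper`, `n_points`.
#' @export
fit_timecourses <- function(data, protocols, free = default_free_params(),
                            base_params = table1_parameters(),
                            lower = NULL, upper = NULL, bound_span = 10,
                            n_starts = 16, seed = 1, maxiter = 100,
                            ssne_tol = 1e-8, sd_floor_frac = 0.001) {
  if (is.list(data) && !inherits(data, "tim2_dataset"))
    data <- do.call(rbind, lapply(data, as.data.frame))
  data <- as_timecourse_dataset(as.data.frame(data))
  validate_parameters(base_params)
  if (!all(free %in% names(base_params)))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, names(base_params)), collapse = ", "),
         call. = FALSE)

  bd <- .default_bounds(free, base_params, span = bound_span)
  if (!is.null(lower)) bd$lower[names(lower)] <- lower
  if (!is.null(upper)) bd$upper[names(upper)] <- upper
  if (any(bd$lower <= 0) || any(bd$upper <= bd$lower))
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  llo <- log(bd$lower)
  lup <- log(bd$upper)

  apply_free <- function(theta_log) {
    p <- base_params
    vals <- exp(theta_log)
    for (i in seq_along(free)) p[[free[i]]] <- vals[i]
    # conservation default tracks a fitted surviving fraction
    if ("alpha9" %in% free && !"alpha10" %in% free)
      p$alpha10 <- 1 - p$alpha9
    p
  }
  resid_fn <- function(theta_log) {
    p <- apply_free(theta_log)
    m <- predict_dataset(p, protocols, data)
    .ssne_residuals(m, data, sd_floor_frac)
  }

  set.seed(as.integer(seed))
  design <- lhs::randomLHS(n_starts, length(free))
  starts <- t(apply(design, 1, function(u) llo + u * (lup - llo)))
  if (length(free) == 1) starts <- matrix(starts, ncol = 1)

  best <- NULL
  trace <- data.frame(start = seq_len(n_starts), ssne = NA_real_,
                      converged = FALSE)
  for (s in seq_len(n_starts)) {
    fit_s <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = llo, upper = lup,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ssne_tol,
                           ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit_s)) next
    val <- sum(fit_s$fvec^2)
    trace$ssne[s] <- val
    trace$converged[s] <- fit_s$info %in% 1:4
    if (is.null(best) || val < best$val)
      best <- list(val = val, par = fit_s$par, info = fit_s$info)
  }
  if (is.null(best))
    stop("optimization error: all ", n_starts, " starts failed; best ",
         "residual unavailable", call. = FALSE)

  # polish: restarting Levenberg-Marquardt resets its trust region, which
  # lets it creep further along near-flat valleys (e.g. the gamma7/K47
  # product ridge) than a single run will
  for (k in seq_len(5)) {
    ft <- tryCatch(
      minpack.lm::nls.lm(par = best$par, lower = llo, upper = lup,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = ssne_tol,
                           ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ft)) break
    val <- sum(ft$fvec^2)
    if (val < best$val - max(ssne_tol, 1e-10 * best$val))
      best <- list(val = val, par = ft$par, info = ft$info)
    else break
  }

  est <- exp(best$par)
  names(est) <- free

  # flat-objective (unidentifiability) probe at the optimum
  unident <- character(0)
  for (i in seq_along(free)) {
    probe <- best$par
    probe[i] <- min(probe[i] + log(1.5), lup[i])
    if (probe[i] == best$par[i]) probe[i] <- max(best$par[i] - log(1.5), llo[i])
    dval <- abs(sum(resid_fn(probe)^2) - best$val)
    if (dval <= 1e-8 * (1 + best$val)) unident <- c(unident, free[i])
  }
  if (length(unident) > 0)
    warning("parameter(s) not identifiable from these data: ",
            paste(unident, collapse = ", "), call. = FALSE)

  structure(list(estimates = est, ssne = best$val, per_start = trace,
                 converged = any(trace$converged, na.rm = TRUE),
                 unidentifiable = unident, seed = as.integer(seed),
                 free = free, lower = bd$lower, upper = bd$upper,
                 n_points = nrow(data)),
            class = "tim2_fit")
}

#' @export
print.tim2_fit <- function(x, ...) {
  cat("SSNE co-fit over", x$n_points, "points; SSNE =",
      format(x$ssne, digits = 6), "\n")
  print(signif(x$estimates, 5))
  if (length(x$unidentifiable) > 0)
    cat("unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Derived kinetic quantities
#'
#' Converts rate constants into the interpretable quantities the model
#' yields: the per-minute probability that a free membrane receptor binds
#' Fe-HFt (`100 * alpha7_Ftex`), the mean time for a bound complex to
#' form an endosome at low ferritin (`1 / gamma7`), the percentage of
#' internalised HFt surviving endocytosis (`100 * alpha9`), the LIP
#' export rate (`100 * alpha6_x3_eff` percent per minute), and the slow
#' second-phase HFt degradation expressed as percent loss per hour
#' (`100 * (1 - exp(-gamma9 * 60))`).
#'
#' @param params a `tim2_parameters` object (or a `tim2_fit`, whose
#'   estimates are merged over the packaged reference values).
#' @return A `tim2_derived` object.
#' @export
#' @examples
#' derive_quantities(table1_parameters())
derive_quantities <- function(params) {
  if (inherits(params, "tim2_fit")) {
    p <- table1_parameters()
    for (nm in names(params$estimates)) p[[nm]] <- params$estimates[[nm]]
    params <- p
  }
  validate_parameters(params)
  if (params$gamma7 <= 0)
    stop("undefined mean endosome time: gamma7 must be > 0", call. = FALSE)
  q <- list(binding_probability_pct = 100 * params$alpha7_Ftex,
            mean_endosome_time_min = 1 / params$gamma7,
            surviving_hft_pct = 100 * params$alpha9,
            lip_export_pct_per_min = 100 * params$alpha6_x3_eff,
            phase_two_pct_per_h = 100 * (1 - exp(-params$gamma9 * 60)))
  stopifnot(all(unlist(q) >= 0), q$surviving_hft_pct <= 100)
  class(q) <- "tim2_derived"
  q
}

#' @export
print.tim2_derived <- function(x, ...) {
  cat(format_derived(x), sep = "\n")
  invisible(x)
}

#' Human-readable report of derived quantities
#'
#' Formats a `tim2_derived` object with the conventional rounding: one
#' decimal place for percentages per minute and minutes, integer percent
#' for the surviving fraction.
#'
#' @param q a `tim2_derived` object.
#' @return Character vector of report lines.
#' @export
format_derived <- function(q) {
  stopifnot(inherits(q, "tim2_derived"))
  c(sprintf("TIM-2 binding probability with Fe-HFt: %.1f%% per min",
            q$binding_probability_pct),
    sprintf("Mean endosome formation time: %.1f min",
            round(q$mean_endosome_time_min, 1)),
    sprintf("HFt surviving endocytosis: %.0f%%",
            round(q$surviving_hft_pct)),
    sprintf("LIP export rate: %.1f%% per min",
            q$lip_export_pct_per_min),
    sprintf("Second-phase HFt degradation: %.1f%% per h",
            q$phase_two_pct_per_h))
}

#' Synthetic-data parameter recovery study
#'
#' The identifiability surface that stands in for refitting the
#' laboratory points: over `n_seeds` seeds, generate triplicate synthetic
#' uptake (TIM-2 and vector) and storage datasets at the generating
#' parameters with the given noise, co-fit the free parameters by SSNE
#' minimisation, and summarise per-seed estimates and relative errors.
#'
#' @param n_seeds number of independent synthetic datasets.
#' @param seed base seed; per-dataset seeds are drawn from it.
#' @param params generating parameters.
#' @param cv,sd_floor,n_reps noise settings (see [noise_model()]).
#' @param free free-parameter set.
#' @param n_starts Latin-hypercube starts per fit.
#' @param bound_span bound span factor (see [fit_timecourses()]).
#' @param maxiter per-start iteration cap.
#' @return A `tim2_recovery` object: list with `estimates` (n_seeds x
#'   n_free data frame), `truth`, `median_estimates`,
#'   `median_rel_error`, `seeds`.
#' @export
recovery_study <- function(n_seeds = 20, seed = 1,
                           params = table1_parameters(),
                           cv = 0.10, sd_floor = 0, n_reps = 3,
                           free = default_free_params(),
                           n_starts = 16, bound_span = 10, maxiter = 100) {
  protocols <- list(uptake_tim2 = build_protocol("uptake", "tim2"),
                    uptake_vector = build_protocol("uptake", "vector"),
                    storage_tim2 = build_protocol("storage", "tim2"))
  nm <- noise_model(cv = cv, sd_floor = sd_floor)
  set.seed(as.integer(seed))
  seeds <- sample.int(1000000L, n_seeds * 4L)
  est <- matrix(NA_real_, n_seeds, length(free),
                dimnames = list(NULL, free))
  for (i in seq_len(n_seeds)) {
    s4 <- seeds[(i - 1) * 4 + 1:4]
    data <- rbind(
      generate_dataset(params, protocols$uptake_tim2, nm, n_reps,
                       seed = s4[1]),
      generate_dataset(params, protocols$uptake_vector, nm, n_reps,
                       seed = s4[2]),
      generate_dataset(params, protocols$storage_tim2, nm, n_reps,
                       seed = s4[3]))
    fit <- fit_timecourses(as_timecourse_dataset(data), protocols,
                           free = free, base_params = params,
                           bound_span = bound_span, n_starts = n_starts,
                           seed = s4[4], maxiter = maxiter)
    est[i, ] <- fit$estimates[free]
  }
  truth <- vapply(free, function(nm) params[[nm]], 0)
  med <- apply(est, 2, stats::median)
  structure(list(estimates = as.data.frame(est), truth = truth,
                 median_estimates = med,
                 median_rel_error = apply(abs(sweep(est, 2, truth) /
                                                rep(truth, each = n_seeds)),
                                          2, stats::median),
                 seeds = seeds, n_seeds = n_seeds),
            class = "tim2_recovery")
}

#' @export
print.tim2_recovery <- function(x, ...) {
  cat("Parameter recovery over", x$n_seeds, "synthetic datasets\n")
  print(data.frame(truth = signif(x$truth, 4),
                   median_estimate = signif(x$median_estimates, 4),
                   median_rel_error = signif(x$median_rel_error, 3)))
  invisible(x)
}
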