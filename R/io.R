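#' Timecourse dataset constructor and validator
#'
#' A timecourse dataset is a data frame with one row per measured point
#' and columns `experiment` (e.g. `"uptake_tim2"`), `observable` (one of
#' [observable_ids]), `time_min` (reported time in minutes), `mean`,
#' `sd` and `n` (replicate summary of the 55Fe signal in pmol per 1e6
#' cells). Row order is preserved.
#'
#' @param df a data frame with the columns above.
#' @return The validated data frame with class `tim2_dataset`.
#' @export
as_timecourse_dataset <- function(df) {
  req <- c("experiment", "observable", "time_min", "mean", "sd", "n")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("parse error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, req]
  for (col in c("time_min", "mean", "sd", "n")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("parse error: non-numeric value in column '", col, "' (row ",
           ifelse(is.na(bad), "?", bad), ")", call. = FALSE)
    }
  }
  if (any(df$sd < 0))
    stop("parse error: negative sd (row ", which(df$sd < 0)[1], ")",
         call. = FALSE)
  if (any(df$n < 1))
    stop("parse error: replicate count n must be >= 1 (row ",
         which(df$n < 1)[1], ")", call. = FALSE)
  bad_obs <- !df$observable %in% observable_ids
  if (any(bad_obs))
    stop("parse error: unknown observable '", df$observable[bad_obs][1],
         "' (row ", which(bad_obs)[1], ")", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("tim2_dataset", "data.frame")
  df
}

#' Read and write timecourse datasets
#'
#' Comma-delimited tables with header
#' `experiment, observable, time_min, mean, sd, n`.
#'
#' @param path file path.
#' @return `read_timecourse()` returns a `tim2_dataset`;
#'   `write_timecourse()` returns `path` invisibly.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path))
    stop("parse error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_timecourse_dataset(df)
}

#' @rdname read_timecourse
#' @param data a `tim2_dataset`.
#' @export
write_timecourse <- function(data, path) {
  stopifnot(inherits(data, "tim2_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory's observables as a delimited table
#'
#' One row per (observable, time) with columns `experiment`,
#' `observable`, `time_min`, `value`.
#'
#' @param trajectory a `tim2_trajectory`.
#' @param path output CSV path.
#' @param observables observable ids; defaults to the protocol's own.
#' @return The written data frame, invisibly.
#' @export
write_observables <- function(trajectory, path,
                              observables = NULL) {
  pr <- attr(trajectory, "protocol")
  if (is.null(observables)) observables <- pr$observables
  tab <- do.call(rbind, lapply(observables, function(obs) {
    tc <- observe(trajectory, obs)
    data.frame(experiment = pr$experiment, observable = obs,
               time_min = tc$time_min, value = tc$value)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Write a fit result as JSON
#'
#' Stores estimates, the SSNE optimum, the per-start trace, bounds, the
#' seed and convergence information.
#'
#' @param fit a `tim2_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "tim2_fit"))
  out <- list(estimates = as.list(fit$estimates), ssne = fit$ssne,
              converged = fit$converged, seed = fit$seed,
              unidentifiable = fit$unidentifiable,
              bounds = list(lower = as.list(fit$lower),
                            upper = as.list(fit$upper)),
              per_start = fit$per_start, n_points = fit$n_points)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
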