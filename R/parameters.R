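#' Model parameters for the TIM-2 iron-handling system
#'
#' Constructs and validates the full parameter set of the extended
#' iron-homeostasis model: the core labile-iron-pool (LIP) / TfR1 /
#' ferroportin / endogenous-ferritin / IRP subsystem plus the TIM-2
#' receptor pathway (binding of exogenous iron-loaded H-ferritin,
#' endocytosis, receptor recycling, and lysosomal degradation).
#'
#' Only lumped products are identifiable from tracer timecourses, so the
#' external-concentration factors are folded into single first-order
#' coefficients: `alpha7_Ftex` (receptor-ligand combination, the product of
#' the rate constant and the external Fe-HFt level), `alpha1_Feex_x2`
#' (TIM-2-independent uptake), and `alpha6_x3_eff` (ferroportin-mediated
#' LIP export).
#'
#' Tracer-conservation defaults route all iron released by HFt degradation
#' into the LIP: `alpha10 = 1 - alpha9` (the share degraded at endosome
#' dissolution) and `alpha11 = 1` (slow degradation of surviving HFt).
#' Both can be overridden for sensitivity analysis, at the cost of exact
#' tracer mass balance.
#'
#' @param alpha1_Feex_x2 effective direct (TIM-2-independent) uptake
#'   coefficient, per min, applied first-order to unbound media label.
#' @param alpha2,gamma2 TfR1 production and decay rates, per min.
#' @param alpha3,gamma3,gammah_Hep ferroportin production, decay, and lumped
#'   hepcidin-mediated decay rates, per min.
#' @param alpha4_storage maximum LIP to endogenous-ferritin storage rate,
#'   per min.
#' @param gamma4 endogenous-ferritin iron release/decay constant, per min.
#' @param alpha5,gamma5 IRP production and decay rates, per min.
#' @param alpha6_x3_eff effective first-order LIP export coefficient
#'   (ferroportin route), per min.
#' @param alpha7_Ftex lumped TIM-2/Fe-HFt combination coefficient, per min.
#' @param gamma6 endosome-to-membrane TIM-2 recycling rate, per min.
#' @param gamma7 endosome formation (processing) rate at low intracellular
#'   ferritin, per min.
#' @param alpha9 fraction of internalised HFt surviving endocytosis,
#'   unitless in \[0, 1\].
#' @param gamma9 intracellular degradation rate of surviving exogenous HFt,
#'   per min.
#' @param alpha10 fraction of iron from endosomal HFt degradation routed to
#'   the LIP; defaults to `1 - alpha9`.
#' @param alpha11 fraction of iron from slow degradation of surviving HFt
#'   routed to the LIP; defaults to 1.
#' @param k15,k52,k53,k54 activation/inhibition thresholds of the core
#'   model, pool units.
#' @param K47 endosome-formation saturation threshold, pmol per 1e6 cells:
#'   the intracellular ferritin level at which the endocytosis rate is
#'   halved.
#' @param x6_total total membrane TIM-2 binding capacity of TIM-2
#'   transfectants, pmol Fe-equivalent per 1e6 cells. The default is
#'   calibrated from the initial uptake rate divided by the combination
#'   coefficient (1.4 / 0.166).
#' @param frozen_core if `TRUE` (the default), the TfR1/Fpn/IRP pools are
#'   held at their pre-treatment equilibrium values so the non-TIM-2 part
#'   of the system stays in its linear regime; if `FALSE` the full core
#'   equations are integrated.
#'
#' @return An object of class `tim2_parameters` (a named list).
#' @seealso [table1_parameters()] for the packaged reference values,
#'   [iron_rhs()] for the equations the parameters feed.
#' @export
#' @examples
#' p <- model_parameters()
#' p$gamma7
model_parameters <- function(alpha1_Feex_x2 = 0.00015,
                             alpha2 = 1, gamma2 = 1,
                             alpha3 = 1, gamma3 = 1, gammah_Hep = 0,
                             alpha4_storage = 0.001, gamma4 = 0.000125,
                             alpha5 = 1, gamma5 = 1,
                             alpha6_x3_eff = 0.0019,
                             alpha7_Ftex = 0.166,
                             gamma6 = 0.0142,
                             gamma7 = 0.118,
                             alpha9 = 0.283,
                             gamma9 = 0.00031,
                             alpha10 = NULL,
                             alpha11 = 1,
                             k15 = 1, k52 = 1, k53 = 1, k54 = 1,
                             K47 = 0.11,
                             x6_total = 1.4 / 0.166,
                             frozen_core = TRUE) {
  if (is.null(alpha10)) alpha10 <- 1 - alpha9
  p <- list(alpha1_Feex_x2 = alpha1_Feex_x2,
            alpha2 = alpha2, gamma2 = gamma2,
            alpha3 = alpha3, gamma3 = gamma3, gammah_Hep = gammah_Hep,
            alpha4_storage = alpha4_storage, gamma4 = gamma4,
            alpha5 = alpha5, gamma5 = gamma5,
            alpha6_x3_eff = alpha6_x3_eff,
            alpha7_Ftex = alpha7_Ftex,
            gamma6 = gamma6, gamma7 = gamma7,
            alpha9 = alpha9, gamma9 = gamma9,
            alpha10 = alpha10, alpha11 = alpha11,
            k15 = k15, k52 = k52, k53 = k53, k54 = k54,
            K47 = K47, x6_total = x6_total,
            frozen_core = isTRUE(frozen_core))
  class(p) <- "tim2_parameters"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rate constants, positivity of thresholds,
#' and the \[0, 1\] range of the branching fractions `alpha9`, `alpha10`
#' and `alpha11`.
#'
#' @param p a `tim2_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "tim2_parameters"))
  rates <- c("alpha1_Feex_x2", "alpha2", "gamma2", "alpha3", "gamma3",
             "gammah_Hep", "alpha4_storage", "gamma4", "alpha5", "gamma5",
             "alpha6_x3_eff", "alpha7_Ftex", "gamma6", "gamma7", "gamma9",
             "x6_total")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid parameter: '", nm, "' must be a non-negative number",
           call. = FALSE)
  }
  for (nm in c("k15", "k52", "k53", "k54", "K47")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("invalid parameter: threshold '", nm, "' must be > 0",
           call. = FALSE)
  }
  for (nm in c("alpha9", "alpha10", "alpha11")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid parameter: fraction '", nm, "' must lie in [0, 1]",
           call. = FALSE)
  }
  invisible(p)
}

#' Reference parameter set extracted from the three tracer experiments
#'
#' Reads the packaged `table1.json` file: the eight controlling parameters
#' of the TIM-2 pathway (combination coefficient, endosome formation rate,
#' recycling rate, surviving fraction, slow HFt degradation rate,
#' endosome-formation saturation threshold, direct uptake coefficient, and
#' ferroportin export coefficient) together with documented defaults for
#' the core-model constants.
#'
#' @param path path to a parameter JSON file; defaults to the packaged
#'   reference set.
#' @return A `tim2_parameters` object.
#' @export
#' @examples
#' table1_parameters()$alpha7_Ftex
table1_parameters <- function(path = system.file("extdata", "table1.json",
                                                 package = "tim2iron")) {
  read_parameters(path)
}

#' Read and write parameter files
#'
#' Parameters are stored as a flat JSON object mapping field names of
#' [model_parameters()] to numbers. Unknown names are rejected; omitted
#' names take the documented defaults.
#'
#' @param path file path.
#' @return `read_parameters()` returns a `tim2_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_parameters))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown parameter name(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(model_parameters, raw)
}

#' @rdname read_parameters
#' @param p a `tim2_parameters` object to write.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.tim2_parameters <- function(x, ...) {
  cat("TIM-2 iron-handling model parameters\n")
  num <- vapply(x[setdiff(names(x), "frozen_core")], as.numeric, 0)
  print(num)
  cat("frozen_core:", x$frozen_core, "\n")
  invisible(x)
}

# Pack a parameter set plus simulation flags into the flat numeric vector
# consumed by the compiled rhs. Order must match src/tim2_model.c.
.pack_parms <- function(p, tim2_present = TRUE, media_ref = 0,
                        ferritin_media = FALSE, literal_hill = FALSE) {
  c(alpha1_Feex_x2 = p$alpha1_Feex_x2,
    alpha2 = p$alpha2, gamma2 = p$gamma2,
    alpha3 = p$alpha3, gamma3 = p$gamma3, gammah_Hep = p$gammah_Hep,
    alpha4_storage = p$alpha4_storage, gamma4 = p$gamma4,
    alpha5 = p$alpha5, gamma5 = p$gamma5,
    alpha6_x3_eff = p$alpha6_x3_eff,
    alpha7_Ftex = p$alpha7_Ftex,
    gamma6 = p$gamma6, gamma7 = p$gamma7,
    alpha9 = p$alpha9, gamma9 = p$gamma9,
    alpha10 = p$alpha10, alpha11 = p$alpha11,
    k15 = p$k15, k52 = p$k52, k53 = p$k53, k54 = p$k54,
    K47 = p$K47,
    frozen = as.numeric(p$frozen_core),
    tim2 = as.numeric(tim2_present),
    media_ref = media_ref,
    ferritin_media = as.numeric(ferritin_media),
    literal_hill = as.numeric(literal_hill))
}
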