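#' @useDynLib tim2iron, .registration = TRUE
NULL

# State variable names, in integration order (must match src/tim2_model.c).
.state_names <- c("x1", "x2", "x3", "x4", "x5", "x6", "x7", "x8", "x9",
                  "media_unbound", "media_exported")

#' Construct a state vector
#'
#' The state of the tracer model: labelled iron in the labile iron pool
#' (`x1`), TfR1 (`x2`), ferroportin (`x3`), labelled iron in endogenous
#' H-ferritin (`x4`), active IRPs (`x5`), free membrane TIM-2 binding
#' capacity (`x6`), iron in membrane TIM-2/Fe-HFt complexes (`x7`), TIM-2
#' capacity in endosomes (`x8`), iron in surviving exogenous HFt (`x9`),
#' plus two media bookkeeping pools for label not yet cell-associated and
#' cumulative exported label. Labelled pools are in pmol 55Fe-equivalent
#' per 1e6 cells; x2/x3/x5 are in model units; TIM-2 pools are in iron
#' binding-capacity equivalents so that binding moves label conservatively.
#'
#' @param x1,x2,x3,x4,x5,x6,x7,x8,x9 pool levels (see Description).
#' @param media_unbound,media_exported media bookkeeping pools.
#' @return A named numeric vector of length 11.
#' @export
state_vector <- function(x1 = 0, x2 = 0, x3 = 0, x4 = 0, x5 = 0,
                         x6 = 0, x7 = 0, x8 = 0, x9 = 0,
                         media_unbound = 0, media_exported = 0) {
  y <- c(x1 = x1, x2 = x2, x3 = x3, x4 = x4, x5 = x5, x6 = x6, x7 = x7,
         x8 = x8, x9 = x9, media_unbound = media_unbound,
         media_exported = media_exported)
  .check_state(y)
  y
}

.check_state <- function(y, tol = 1e-8) {
  if (!is.numeric(y) || length(y) != length(.state_names))
    stop("state must be a numeric vector of length ", length(.state_names),
         call. = FALSE)
  if (any(!is.finite(y)))
    stop("state contains non-finite entries", call. = FALSE)
  if (any(y < -tol))
    stop("state-domain error: negative pool(s): ",
         paste(.state_names[y < -tol], collapse = ", "), call. = FALSE)
  invisible(y)
}

#' Hill-type promotion and inhibition rates
#'
#' The two saturating rate laws of the model: `hill_promote()` is the
#' linear-to-saturation form `alpha * x / (k + x)` used for promoting
#' effects, and `hill_inhibit()` is the constant-to-suppression form
#' `alpha * k / (k + x)` used for inhibiting effects (in particular the
#' suppression of endocytosis by intracellular ferritin at threshold
#' `K47`, where the rate is halved when `x == k`).
#'
#' @param x pool level (>= 0).
#' @param alpha maximum rate (>= 0).
#' @param k activation/inhibition threshold (> 0).
#' @return The rate, a value in `[0, alpha]`.
#' @export
#' @examples
#' hill_promote(1, 0.5, 1)   # alpha/2 at threshold
#' hill_inhibit(0, 0.5, 1)   # unsuppressed limit: alpha
hill_promote <- function(x, alpha, k) {
  .check_hill_args(x, alpha, k)
  alpha * x / (k + x)
}

#' @rdname hill_promote
#' @export
hill_inhibit <- function(x, alpha, k) {
  .check_hill_args(x, alpha, k)
  alpha * k / (k + x)
}

.check_hill_args <- function(x, alpha, k) {
  if (any(k <= 0)) stop("invalid parameter: threshold k must be > 0",
                        call. = FALSE)
  if (any(alpha < 0)) stop("invalid parameter: alpha must be >= 0",
                           call. = FALSE)
  if (any(x < 0)) stop("invalid argument: pool level x must be >= 0",
                       call. = FALSE)
  invisible(NULL)
}

#' Time derivative of the tracer model (reference R implementation)
#'
#' Evaluates the right-hand side of the extended iron-homeostasis system:
#' the core LIP/TfR1/Fpn/ferritin/IRP equations plus the TIM-2 pathway
#' (receptor-ligand combination, ferritin-suppressed endocytosis, receptor
#' recycling, HFt survival and degradation) and the media bookkeeping
#' pools. [simulate_protocol()] integrates the identical equations through
#' compiled code; this R implementation is the readable reference and is
#' usable directly with [deSolve::lsoda()] via `func = iron_rhs`.
#'
#' The processing flux `F = hill_inhibit(x4 + x9, gamma7, K47) * x7` is
#' applied consistently in the x7 loss, x8 gain, x9 gain (times `alpha9`)
#' and LIP gain (times `alpha10`) terms, so the x7 outflow equals the sum
#' of its destinations; setting `literal_hill = TRUE` instead uses the
#' unsuppressed flux `gamma7 * x7` in the x9/LIP gain terms.
#'
#' @param t time (min); the system is autonomous, `t` is ignored.
#' @param state a state vector as from [state_vector()].
#' @param params a `tim2_parameters` object.
#' @param tim2_present if `FALSE`, the receptor pools are inert
#'   (vector-control cells).
#' @param media_ref reference media label level of the current phase; the
#'   receptor binding coefficient is scaled by
#'   `media_unbound / media_ref` (clamped to `[0, 1]`) so media depletion
#'   is respected.
#' @param ferritin_media whether the media label is carried by exogenous
#'   Fe-HFt (binding possible); `FALSE` for chase/export media whose label
#'   is not ferritin-bound.
#' @param literal_hill use the unsuppressed processing flux in the x9/LIP
#'   gain terms (see Details).
#' @return A list whose first element is the derivative vector (per min),
#'   as required by deSolve.
#' @export
#' @examples
#' p <- table1_parameters()
#' y <- state_vector(x9 = 1)
#' iron_rhs(0, y, p)[[1]][["x9"]]   # -gamma9
iron_rhs <- function(t, state, params, tim2_present = TRUE, media_ref = 0,
                     ferritin_media = FALSE, literal_hill = FALSE) {
  validate_parameters(params)
  .check_state(state)
  y <- as.list(state)
  p <- params

  frac <- 0
  if (ferritin_media && media_ref > 0)
    frac <- min(1, max(0, y$media_unbound / media_ref))
  bind <- if (tim2_present) p$alpha7_Ftex * y$x6 * frac else 0

  f_proc <- hill_inhibit(y$x4 + y$x9, p$gamma7, p$K47) * y$x7
  f_gain <- if (literal_hill) p$gamma7 * y$x7 else f_proc

  direct  <- p$alpha1_Feex_x2 * y$media_unbound
  storef  <- hill_inhibit(y$x5, p$alpha4_storage, p$k54) * y$x1
  release <- p$gamma4 * y$x4
  export  <- p$alpha6_x3_eff * y$x1

  d <- numeric(length(.state_names))
  names(d) <- .state_names
  d["x1"] <- direct + release - export - storef +
    p$alpha10 * f_gain + p$alpha11 * p$gamma9 * y$x9
  if (!p$frozen_core) {
    d["x2"] <- hill_promote(y$x5, p$alpha2, p$k52) - p$gamma2 * y$x2
    d["x3"] <- hill_inhibit(y$x5, p$alpha3, p$k53) -
      (p$gamma3 + p$gammah_Hep) * y$x3
    d["x5"] <- hill_inhibit(y$x1, p$alpha5, p$k15) - p$gamma5 * y$x5
  }
  d["x4"] <- storef - release
  if (tim2_present) {
    d["x6"] <- p$gamma6 * y$x8 - bind
    d["x7"] <- bind - f_proc
    d["x8"] <- f_proc - p$gamma6 * y$x8
  }
  d["x9"] <- p$alpha9 * f_gain - p$gamma9 * y$x9
  d["media_unbound"] <- -bind - direct
  d["media_exported"] <- export
  list(d)
}

#' Pre-treatment equilibrium state
#'
#' Builds the state the system occupies before an experimental treatment
#' is applied, under the assumption that the cell has reached equilibrium.
#' The regulatory pools (x2, x3, x5) are placed at the steady state of
#' their governing equations evaluated at the baseline LIP level; the free
#' receptor capacity `x6` carries the full TIM-2 total (no ligand yet);
#' labelled pools are zero unless a cell preload is given.
#'
#' A preload (used for the export experiment, where cells are loaded with
#' labelled iron through transferrin before the chase) is partitioned
#' between endogenous ferritin and the LIP according to the
#' storage/release balance `alpha4_eff : gamma4`; with the packaged
#' reference constants (ratio 4:1) this is the 80/20 ferritin/LIP split.
#' The partition is the equilibrium of the fast intracellular
#' storage-release exchange; the slow ferroportin export flux is not
#' zeroed by any distribution of label, so with a preload the returned
#' state is a conditional (fast-subsystem) equilibrium.
#'
#' @param params a `tim2_parameters` object.
#' @param cell_line `"tim2"` (receptor present) or `"vector"` (control,
#'   no TIM-2 capacity).
#' @param preload_cell labelled iron preloaded into the cell, pmol per 1e6
#'   cells.
#' @param media_label labelled iron present in the media, pmol per 1e6
#'   cells.
#' @param tol residual tolerance on the zero-preload equilibrium.
#' @param max_iter iteration cap for the self-consistent solve of the
#'   regulatory pools when `frozen_core = FALSE` and a preload is present.
#' @return A state vector (see [state_vector()]).
#' @export
#' @examples
#' equilibrate(table1_parameters())             # all labelled pools zero
#' equilibrate(table1_parameters(), preload_cell = 10.8)[c("x1", "x4")]
equilibrate <- function(params, cell_line = c("tim2", "vector"),
                        preload_cell = 0, media_label = 0,
                        tol = 1e-9, max_iter = 100) {
  validate_parameters(params)
  cell_line <- match.arg(cell_line)
  if (preload_cell < 0 || media_label < 0)
    stop("preload and media label must be >= 0", call. = FALSE)
  p <- params

  core_at <- function(x1) {
    x5 <- hill_inhibit(x1, p$alpha5, p$k15) / p$gamma5
    list(x5 = x5,
         x2 = hill_promote(x5, p$alpha2, p$k52) / p$gamma2,
         x3 = hill_inhibit(x5, p$alpha3, p$k53) / (p$gamma3 + p$gammah_Hep))
  }
  split_at <- function(x5) {
    a4_eff <- hill_inhibit(x5, p$alpha4_storage, p$k54)
    x4 <- preload_cell * a4_eff / (a4_eff + p$gamma4)
    c(x1 = preload_cell - x4, x4 = x4)
  }

  # Regulatory pools at the pre-treatment baseline (zero labelled LIP).
  # With frozen_core the Hill factors stay at these values by construction;
  # otherwise iterate the x1 <-> x5 fixed point to self-consistency.
  core <- core_at(0)
  lab <- split_at(core$x5)
  if (!p$frozen_core && preload_cell > 0) {
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      core_new <- core_at(lab[["x1"]])
      lab_new <- split_at(core_new$x5)
      delta <- abs(lab_new[["x1"]] - lab[["x1"]])
      core <- core_new
      lab <- lab_new
      if (delta < 1e-12 * (1 + preload_cell)) { converged <- TRUE; break }
    }
    if (!converged)
      stop("equilibration failure: fixed point not reached within ",
           max_iter, " iterations (last change ", format(delta), ")",
           call. = FALSE)
  }

  y <- state_vector(x1 = lab[["x1"]], x2 = core$x2, x3 = core$x3,
                    x4 = lab[["x4"]], x5 = core$x5,
                    x6 = if (cell_line == "tim2") p$x6_total else 0,
                    media_unbound = media_label)

  if (preload_cell == 0 && media_label == 0) {
    resid <- max(abs(iron_rhs(0, y, p, tim2_present = cell_line == "tim2")[[1]]))
    if (resid > tol)
      stop("equilibration failure: residual ", format(resid),
           " exceeds tolerance ", format(tol), call. = FALSE)
  }
  y
}
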