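#' Basal rate parameters of the autophagic flux model
#'
#' The pathway is a linear mass-action chain CYT -> AP -> AL -> sink with
#' three reactions: autophagosome formation (zeroth order from an unlimited
#' cytoplasmic LC3 pool), conversion of autophagosomes (AP) to
#' autophagolysosomes (AL), and lysosomal degradation into a cumulative sink.
#'
#' @param k_form AP formation rate (a.u. per hour, zeroth order).
#' @param k_conv AP -> AL conversion rate constant (per hour).
#' @param k_deg AL degradation rate constant (per hour).
#' @return A named numeric vector of class `flux_params`.
#' @examples
#' flux_params(10, 1, 2)
#' @export
flux_params <- function(k_form, k_conv, k_deg) {
  p <- c(k_form = as.numeric(k_form), k_conv = as.numeric(k_conv),
         k_deg = as.numeric(k_deg))
  if (any(!is.finite(p)) || any(p < 0))
    stop("rate parameters must be finite and >= 0", call. = FALSE)
  structure(p, class = c("flux_params", "numeric"))
}

#' Perturbing-agent modifier table
#'
#' Each row assigns an agent a (target reaction, direction, strength) triple.
#' An active agent multiplies its target's basal rate by `1 + strength` when
#' activating and by `1 / (1 + strength)` when inhibiting; effects of several
#' active agents on the same reaction compose by product. `strength = 0` is a
#' no-op, so absent effects need not be listed.
#'
#' @param agent Character vector of agent identifiers (e.g. "BAF", "STV").
#' @param target Reaction targeted: "formation", "conversion" or "degradation".
#' @param direction "activate" or "inhibit".
#' @param strength Non-negative dimensionless effect size (NA = free, to be
#'   fitted).
#' @return A data frame of class `flux_modifiers`.
#' @examples
#' modifier_table("BAF", "conversion", "inhibit", 9)
#' @export
modifier_table <- function(agent = character(), target = character(),
                           direction = character(), strength = NA_real_) {
  if (length(agent) == 0) {
    m <- data.frame(agent = character(), target = character(),
                    direction = character(), strength = numeric(),
                    stringsAsFactors = FALSE)
    class(m) <- c("flux_modifiers", "data.frame")
    return(m)
  }
  m <- data.frame(agent = as.character(agent), target = as.character(target),
                  direction = as.character(direction),
                  strength = as.numeric(strength),
                  stringsAsFactors = FALSE)
  validate_modifiers(m)
  class(m) <- c("flux_modifiers", "data.frame")
  m
}

validate_modifiers <- function(m) {
  stopifnot(is.data.frame(m))
  needed <- c("agent", "target", "direction", "strength")
  if (!all(needed %in% names(m)))
    stop("modifier table needs columns agent, target, direction, strength",
         call. = FALSE)
  if (nrow(m) == 0) return(invisible(m))
  if (!all(m$target %in% c("formation", "conversion", "degradation")))
    stop("modifier target must be formation, conversion or degradation",
         call. = FALSE)
  if (!all(m$direction %in% c("activate", "inhibit")))
    stop("modifier direction must be activate or inhibit", call. = FALSE)
  if (any(!is.na(m$strength) & m$strength < 0))
    stop("modifier strengths must be >= 0", call. = FALSE)
  if (anyDuplicated(m[, c("agent", "target")]))
    stop("an agent may carry at most one modifier per reaction", call. = FALSE)
  invisible(m)
}

validate_activity <- function(activity) {
  if (is.null(activity)) return(numeric(0))
  a <- unlist(activity)
  if (is.null(names(a)) && length(a) > 0)
    stop("activity vector must be named by agent", call. = FALSE)
  if (any(!a %in% c(0, 1)))
    stop("activities must be coded exactly 0 or 1", call. = FALSE)
  a
}

#' Effective reaction rates under a perturbation
#'
#' Applies the multiplicative modifier law to the basal rates: each active
#' modifier scales its target reaction by `(1 + s)` (activate) or
#' `1 / (1 + s)` (inhibit), composing by product across agents. With all
#' activities 0 the basal rates are returned unchanged.
#'
#' @param params A [flux_params()] vector.
#' @param modifiers A [modifier_table()] (strengths must be concrete).
#' @param activity Named 0/1 vector of agent activities; agents absent from
#'   the vector are treated as inactive.
#' @return Named numeric vector `c(r_form, r_conv, r_deg)`.
#' @examples
#' p <- flux_params(1, 1, 1)
#' m <- modifier_table("BAF", "conversion", "inhibit", 9)
#' effective_rates(p, m, c(BAF = 1))  # r_conv = 0.1
#' @export
effective_rates <- function(params, modifiers = NULL, activity = NULL) {
  a <- validate_activity(activity)
  r <- c(r_form = unname(params[["k_form"]]),
         r_conv = unname(params[["k_conv"]]),
         r_deg  = unname(params[["k_deg"]]))
  if (is.null(modifiers) || nrow(modifiers) == 0) return(r)
  validate_modifiers(modifiers)
  if (any(is.na(modifiers$strength)))
    stop("modifier strengths must be concrete to compute effective rates",
         call. = FALSE)
  slot <- c(formation = 1L, conversion = 2L, degradation = 3L)
  for (i in seq_len(nrow(modifiers))) {
    act <- if (modifiers$agent[i] %in% names(a)) a[[modifiers$agent[i]]] else 0
    if (act == 0) next
    f <- 1 + modifiers$strength[i]
    j <- slot[[modifiers$target[i]]]
    r[j] <- if (modifiers$direction[i] == "activate") r[j] * f else r[j] / f
  }
  r
}

# Vectorised exact trajectories of the chain dAP = F - C*AP, dAL = C*AP - D*AL.
# F, C, D, AP0, AL0, S0 are vectors of length m; times a vector of length T.
# Returns list of m x T matrices AP, AL, SINK. Used both by simulate_flux()
# and, heavily, by the fitting objective (one row per particle x condition),
# so it is written with exactly two exp() array evaluations. Building blocks:
#   phi(c, t) = (1 - e^{-ct}) / c        (limit t at c = 0)
#   psi(c, d, t) = (e^{-ct} - e^{-dt}) / (d - c)   (limit t e^{-ct} at c = d)
# with AP = AP0 e^{-Ct} + F phi(C,t)
#      AL = AL0 e^{-Dt} + C AP0 psi + F (phi(D,t) - psi)
# and SINK from mass balance.
flux_traj_core <- function(F, C, D, AP0, AL0, S0, times) {
  m <- length(F)
  nt <- length(times)
  Tt <- matrix(times, nrow = m, ncol = nt, byrow = TRUE)
  ECt <- exp(-C * Tt)
  EDt <- exp(-D * Tt)
  phiC <- (1 - ECt) / C
  phiD <- (1 - EDt) / D
  Cz <- C == 0
  Dz <- D == 0
  if (any(Cz)) phiC[Cz, ] <- Tt[Cz, ]
  if (any(Dz)) phiD[Dz, ] <- Tt[Dz, ]
  delta <- D - C
  near <- abs(delta) <= 1e-9 * pmax(C, D, 1)
  psi <- (ECt - EDt) / ifelse(near, 1, delta)
  if (any(near))
    psi[near, ] <- Tt[near, , drop = FALSE] *
      exp(-(C[near] + D[near]) / 2 * Tt[near, , drop = FALSE])
  AP <- AP0 * ECt + F * phiC
  AL <- AL0 * EDt + C * AP0 * psi + F * (phiD - psi)
  SINK <- S0 + F * Tt + (AP0 - AP) + (AL0 - AL)
  # guard tiny negative round-off
  SINK[SINK < 0 & SINK > -1e-9] <- 0
  list(AP = AP, AL = AL, SINK = SINK)
}

#' Simulate the autophagic flux model
#'
#' Integrates `dAP/dt = r_form - r_conv AP`, `dAL/dt = r_conv AP - r_deg AL`,
#' `dSINK/dt = r_deg AL` under the effective rates implied by `modifiers` and
#' `activity`. The default method evaluates the exact solution of this linear
#' system; `method = "lsoda"` integrates numerically with [deSolve::lsoda()]
#' (adaptive, stiff-capable) and serves as an independent numerical route.
#'
#' @param params A [flux_params()] vector.
#' @param modifiers Optional [modifier_table()].
#' @param activity Optional named 0/1 activity vector.
#' @param init Named numeric `c(AP=, AL=, SINK=)`, all >= 0. Defaults to the
#'   basal steady state (see [basal_steady_init()]), the state of cells
#'   equilibrated in complete medium before treatment.
#' @param times Strictly increasing, non-negative sampling times (hours).
#' @param method "analytic" (default) or "lsoda".
#' @param rtol,atol Relative/absolute tolerances for the numerical method.
#' @return A data frame with columns `time_h`, `AP`, `AL`, `SINK`; the
#'   effective rates are attached as attribute `"rates"`.
#' @examples
#' tc <- simulate_flux(flux_params(10, 1, 2), times = seq(0, 12, 3))
#' al_ap_ratio(tc)
#' @export
simulate_flux <- function(params, modifiers = NULL, activity = NULL,
                          init = NULL, times = seq(0, 12, by = 3),
                          method = c("analytic", "lsoda"),
                          rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (length(times) < 1 || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  r <- effective_rates(params, modifiers, activity)
  if (is.null(init)) init <- basal_steady_init(params)
  init <- init[c("AP", "AL", "SINK")]
  if (any(is.na(init)) || any(init < 0))
    stop("init must provide non-negative AP, AL and SINK", call. = FALSE)
  if (method == "analytic") {
    tr <- flux_traj_core(r[["r_form"]], r[["r_conv"]], r[["r_deg"]],
                         init[["AP"]], init[["AL"]], init[["SINK"]], times)
    out <- data.frame(time_h = times, AP = tr$AP[1, ], AL = tr$AL[1, ],
                      SINK = tr$SINK[1, ])
  } else {
    rhs <- function(t, y, p) {
      list(c(p[1] - p[2] * y[1],
             p[2] * y[1] - p[3] * y[2],
             p[3] * y[2]))
    }
    t_solve <- if (times[1] > 0) c(0, times) else times
    sol <- try(deSolve::lsoda(y = unname(init), times = t_solve, func = rhs,
                              parms = unname(r), rtol = rtol, atol = atol),
               silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(t_solve) ||
        any(!is.finite(sol)))
      stop(sprintf("integration failed for rates (%.3g, %.3g, %.3g)",
                   r[1], r[2], r[3]), call. = FALSE)
    sol <- sol[match(times, sol[, 1]), , drop = FALSE]
    y <- sol[, 2:4, drop = FALSE]
    if (any(y < -10 * atol))
      warning("negative state excursion beyond tolerance; clamped to 0")
    y[y < 0] <- 0
    out <- data.frame(time_h = times, AP = y[, 1], AL = y[, 2], SINK = y[, 3])
  }
  attr(out, "rates") <- r
  class(out) <- c("flux_timecourse", "data.frame")
  out
}

#' Basal steady state as initial condition
#'
#' The untreated fixed point `AP = k_form / k_conv`, `AL = k_form / k_deg`,
#' `SINK = 0`, modelling cells equilibrated in complete medium before a
#' perturbation is applied at t = 0.
#'
#' @param params A [flux_params()] vector.
#' @return Named numeric `c(AP=, AL=, SINK=)`.
#' @export
basal_steady_init <- function(params) {
  if (params[["k_conv"]] <= 0 || params[["k_deg"]] <= 0)
    stop("basal steady state requires k_conv > 0 and k_deg > 0", call. = FALSE)
  c(AP = unname(params[["k_form"]] / params[["k_conv"]]),
    AL = unname(params[["k_form"]] / params[["k_deg"]]),
    SINK = 0)
}

#' Analytic steady state under a perturbation
#'
#' @inheritParams effective_rates
#' @return Named numeric `c(AP = r_form/r_conv, AL = r_form/r_deg,
#'   ratio = r_conv/r_deg)`.
#' @examples
#' steady_state(flux_params(10, 1, 2))  # AP 10, AL 5, ratio 0.5
#' @export
steady_state <- function(params, modifiers = NULL, activity = NULL) {
  r <- effective_rates(params, modifiers, activity)
  if (r[["r_conv"]] <= 0 || r[["r_deg"]] <= 0)
    stop("no steady state: r_conv and r_deg must be > 0", call. = FALSE)
  if (r[["r_form"]] == 0)
    stop("degenerate steady state: r_form = 0 gives AP = AL = 0 and an ",
         "undefined 0/0 ratio", call. = FALSE)
  c(AP = unname(r[["r_form"]] / r[["r_conv"]]),
    AL = unname(r[["r_form"]] / r[["r_deg"]]),
    ratio = unname(r[["r_conv"]] / r[["r_deg"]]))
}

#' AL/AP ratio along a time course
#'
#' The sensor readout used throughout the assay: mCherry+/GFP- puncta (AL)
#' over mCherry+/GFP+ puncta (AP). Points where AP is below `eps` are
#' returned as `NA` (flagged, not infinite).
#'
#' @param timecourse A data frame with columns `AP` and `AL`.
#' @param eps Threshold below which AP is treated as zero.
#' @return Numeric vector of AL/AP per time point, `NA` where undefined.
#' @export
al_ap_ratio <- function(timecourse, eps = 1e-9) {
  if (NROW(timecourse) == 0) stop("empty time course", call. = FALSE)
  ifelse(timecourse$AP < eps, NA_real_, timecourse$AL / timecourse$AP)
}
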