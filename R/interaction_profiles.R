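#' Live-cell fraction of a well
#'
#' Live cells are the PI-negative cells over the total (Hoechst-positive)
#' cells in the well.
#'
#' @param n_total Total cell count (> 0).
#' @param n_dead PI-positive (dead) cell count, `0 <= n_dead <= n_total`.
#' @return Fraction in `[0, 1]`. Vectorised.
#' @examples
#' live_fraction(100, 25)  # 0.75
#' @export
live_fraction <- function(n_total, n_dead) {
  if (any(n_total == 0)) stop("undefined well: n_total = 0", call. = FALSE)
  if (any(n_dead < 0) || any(n_dead > n_total) || any(n_total < 0))
    stop("need 0 <= n_dead <= n_total", call. = FALSE)
  (n_total - n_dead) / n_total
}

#' Bliss-style drug interaction score
#'
#' Under independence the expected live fraction of a combination is the
#' product of the single-agent live fractions. The score is
#' `expected - observed`: positive means the combination killed more than
#' expected (synergism), negative means less (antagonism).
#'
#' @param live_chemo,live_mod Single-agent live fractions in `[0, 1]`.
#' @param live_combo Observed live fraction of the combination.
#' @param tau Classification threshold on `|score|` (default 0.05).
#' @return List with `expected`, `observed`, `score` and `classification`
#'   ("synergism", "antagonism" or "none").
#' @examples
#' interaction_score(0.5, 1.0, 0.2)  # score +0.3, synergism
#' @export
interaction_score <- function(live_chemo, live_mod, live_combo, tau = 0.05) {
  v <- c(live_chemo, live_mod, live_combo)
  if (any(v < 0) || any(v > 1))
    stop("live fractions must be in [0, 1]", call. = FALSE)
  expected <- live_chemo * live_mod
  score <- expected - live_combo
  cls <- if (score > tau) "synergism" else if (score < -tau) "antagonism"
         else "none"
  list(expected = expected, observed = live_combo, score = score,
       classification = cls)
}

#' Fold increase over the untreated control
#'
#' @param signal Measured signal (e.g. calreticulin or ATP readout).
#' @param control_signal Untreated-control signal (> 0).
#' @return `signal / control_signal`. Vectorised over `signal`.
#' @export
fold_change <- function(signal, control_signal) {
  if (any(control_signal <= 0))
    stop("control signal must be > 0", call. = FALSE)
  signal / control_signal
}

#' Calibrate and invert an ATP standard curve
#'
#' Fits `signal ~ concentration` by ordinary least squares on the standards
#' (the kit's calibration points, e.g. 1, 5, 100, 250, 500 and 1000 uM) and
#' inverts it to map readings to concentrations. Readings outside the
#' signal range spanned by the standards are flagged as extrapolated.
#'
#' @param readings Numeric vector of sample signals.
#' @param standards Data frame with columns `conc_uM` and `signal`
#'   (>= 2 distinct concentrations).
#' @return Data frame with `reading`, `conc_uM`, `extrapolated`; the fitted
#'   line is attached as attribute `"calibration"`.
#' @export
atp_concentration <- function(readings, standards) {
  if (!all(c("conc_uM", "signal") %in% names(standards)))
    stop("standards need columns conc_uM and signal", call. = FALSE)
  if (length(unique(standards$conc_uM)) < 2)
    stop("need >= 2 standards with distinct concentrations", call. = FALSE)
  fit <- stats::lm(signal ~ conc_uM, data = standards)
  slope <- stats::coef(fit)[["conc_uM"]]
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps ||
      stats::sd(standards$signal) == 0)
    stop("degenerate standards: signals do not discriminate concentrations",
         call. = FALSE)
  conc <- (readings - stats::coef(fit)[["(Intercept)"]]) / slope
  rng <- range(standards$signal)
  out <- data.frame(reading = readings, conc_uM = conc,
                    extrapolated = readings < rng[1] | readings > rng[2])
  attr(out, "calibration") <- fit
  out
}

parse_pair <- function(condition_id) strsplit(condition_id, "+", fixed = TRUE)

#' Interaction and DAMP heatmap table
#'
#' Builds the tidy chemo x modulator matrix behind the interaction heatmaps:
#' per-condition live fractions are reduced to the median across replicates,
#' Bliss scores are computed for every chemo+modulator pair from the single
#' agent medians, and (optionally) DAMP fold changes over the untreated
#' control are added per marker. Conditions are labelled `"CHEMO"`,
#' `"MOD"` and `"CHEMO+MOD"`; the untreated control is `control_id`.
#'
#' @param viability Data frame with columns `condition_id`, `n_total`,
#'   `n_dead`; several rows per condition are treated as replicates.
#' @param chemo,modulators Agent name vectors defining the matrix axes.
#' @param damps Optional data frame with columns `marker`, `condition_id`,
#'   `signal` (replicate rows allowed).
#' @param control_id Label of the untreated condition (default "CM").
#' @param tau Classification threshold for [interaction_score()].
#' @return Tidy data frame: `block` ("viability", "interaction" or
#'   `"damp_<marker>"`), `chemo`, `modulator`, `value`, `classification`.
#' @export
build_heatmap_table <- function(viability, chemo, modulators, damps = NULL,
                                control_id = "CM", tau = 0.05) {
  lf <- live_fraction(viability$n_total, viability$n_dead)
  med <- tapply(lf, viability$condition_id, stats::median)
  need <- c(chemo, modulators,
            as.vector(outer(chemo, modulators, paste, sep = "+")))
  missing <- setdiff(need, names(med))
  if (length(missing))
    stop("missing conditions (single-agent controls or pairs): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- list()
  for (d in c(chemo, modulators))
    rows[[length(rows) + 1]] <- data.frame(
      block = "viability", chemo = if (d %in% chemo) d else NA,
      modulator = if (d %in% modulators) d else NA,
      value = unname(med[[d]]), classification = NA)
  for (d in chemo) for (m in modulators) {
    sc <- interaction_score(med[[d]], med[[m]], med[[paste0(d, "+", m)]],
                            tau = tau)
    rows[[length(rows) + 1]] <- data.frame(
      block = "interaction", chemo = d, modulator = m, value = sc$score,
      classification = sc$classification)
  }
  if (!is.null(damps) && nrow(damps)) {
    for (mk in unique(damps$marker)) {
      dk <- damps[damps$marker == mk, ]
      dmed <- tapply(dk$signal, dk$condition_id, stats::median)
      if (!control_id %in% names(dmed))
        stop("missing untreated control '", control_id, "' for marker ", mk,
             call. = FALSE)
      for (d in chemo) for (m in modulators) {
        cid <- paste0(d, "+", m)
        if (!cid %in% names(dmed)) next
        rows[[length(rows) + 1]] <- data.frame(
          block = paste0("damp_", mk), chemo = d, modulator = m,
          value = unname(fold_change(dmed[[cid]], dmed[[control_id]])),
          classification = NA)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
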