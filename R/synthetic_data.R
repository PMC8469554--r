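#' Default perturbation condition panel
#'
#' The single and double perturbations of the kinetic assay: complete medium
#' (CM) and starvation (STV), each with and without bafilomycin (BAF); each
#' of the five modulators (RAP, TOR, WRT, SPA, HCQ) alone; each
#' chemotherapeutic drug (EPI, CIS, PAC) alone; and all 15 chemo x modulator
#' pairs. 27 conditions in total.
#'
#' @return Design data frame: `condition_id` plus one 0/1 column per agent.
#' @export
default_panel <- function() {
  agents <- c("STV", "BAF", "RAP", "TOR", "WRT", "SPA", "HCQ",
              "EPI", "CIS", "PAC")
  mods <- c("RAP", "TOR", "WRT", "SPA", "HCQ")
  chemo <- c("EPI", "CIS", "PAC")
  rows <- list(CM = character(0), STV = "STV", BAF = "BAF",
               `STV+BAF` = c("STV", "BAF"))
  for (m in mods) rows[[m]] <- m
  for (d in chemo) rows[[d]] <- d
  for (d in chemo) for (m in mods) rows[[paste0(d, "+", m)]] <- c(d, m)
  design <- as.data.frame(t(vapply(rows, function(on)
    as.numeric(agents %in% on), numeric(length(agents)))))
  names(design) <- agents
  rownames(design) <- NULL
  cbind(data.frame(condition_id = names(rows), stringsAsFactors = FALSE),
        design)
}

#' Compact panel for mode-of-action recovery of a single drug
#'
#' Seven conditions: CM, STV, BAF, STV+BAF, the drug alone, drug+BAF and
#' drug+STV. Enough contrast to identify which reaction the drug perturbs
#' and in which direction.
#'
#' @param drug Drug name (default "EPI").
#' @return Design data frame as in [default_panel()].
#' @export
recovery_panel <- function(drug = "EPI") {
  agents <- c("STV", "BAF", drug)
  rows <- list(CM = character(0), STV = "STV", BAF = "BAF",
               `STV+BAF` = c("STV", "BAF"))
  rows[[drug]] <- drug
  rows[[paste0(drug, "+BAF")]] <- c(drug, "BAF")
  rows[[paste0(drug, "+STV")]] <- c(drug, "STV")
  design <- as.data.frame(t(vapply(rows, function(on)
    as.numeric(agents %in% on), numeric(length(agents)))))
  names(design) <- agents
  rownames(design) <- NULL
  cbind(data.frame(condition_id = names(rows), stringsAsFactors = FALSE),
        design)
}

#' Specification of a synthetic kinetic dataset
#'
#' Defines the ground truth from which time courses are generated: true
#' basal rates, library and drug effect strengths, the condition panel, the
#' 3 h sampling grid over 12 h, and a multiplicative Gaussian noise model.
#'
#' @param params True basal rates ([flux_params()]); default
#'   `flux_params(10, 1, 2)`.
#' @param hypothesis True [mode_hypothesis()] for the drugs in the panel.
#' @param library Known-agent assignments ([modifier_table()]); strengths
#'   set via `library_strength` where `NA`.
#' @param library_strength Effect size for library modulators (default 4,
#'   i.e. a 5-fold rate change).
#' @param drug_strength Effect size for the true drug modes (default 5).
#' @param panel Design data frame; default [default_panel()].
#' @param times Sampling grid in hours (default `seq(0, 12, 3)`).
#' @param cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise (default 0.1).
#' @param replicates Replicates per point (default 3).
#' @param seed RNG seed.
#' @return Object of class `flux_genspec`.
#' @export
generation_spec <- function(params = flux_params(10, 1, 2),
                            hypothesis = mode_hypothesis(c(EPI = "deg-")),
                            library = agent_library(),
                            library_strength = 4, drug_strength = 5,
                            panel = default_panel(),
                            times = seq(0, 12, by = 3),
                            cv = 0.1, replicates = 3, seed = 1) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  lib <- library
  lib$strength[is.na(lib$strength)] <- library_strength
  truth_mods <- if (nrow(hypothesis$assignments) > 0) {
    rbind(as.data.frame(lib), cbind(hypothesis$assignments,
                                    strength = drug_strength))
  } else {
    as.data.frame(lib)
  }
  structure(list(params = params, hypothesis = hypothesis,
                 library = lib, drug_strength = drug_strength,
                 modifiers = truth_mods, panel = panel, times = times,
                 cv = cv, replicates = replicates, seed = seed),
            class = "flux_genspec")
}

#' Generate noisy sensor time courses from a ground-truth model
#'
#' Simulates every panel condition from the basal steady state, then applies
#' multiplicative Gaussian noise `y * (1 + eps)`, `eps ~ N(0, cv)`, clamped
#' at 0, independently per replicate. Observations are the replicate means;
#' per-point SDs are the replicate SDs.
#'
#' @param spec A [generation_spec()].
#' @param cell_line Label stored on the dataset.
#' @return List with `dataset` (a [flux_dataset()]) and `truth` (the
#'   generating parameters, hypothesis and noise-free trajectories).
#' @export
generate_timecourses <- function(spec, cell_line = "synthetic") {
  stopifnot(inherits(spec, "flux_genspec"))
  set.seed(spec$seed)
  agents <- setdiff(names(spec$panel), "condition_id")
  init <- basal_steady_init(spec$params)
  obs <- list()
  clean <- list()
  for (i in seq_len(nrow(spec$panel))) {
    cid <- spec$panel$condition_id[i]
    act <- stats::setNames(as.numeric(spec$panel[i, agents]), agents)
    tc <- simulate_flux(spec$params, spec$modifiers, act, init = init,
                        times = spec$times)
    nT <- length(spec$times)
    reps_AP <- matrix(tc$AP, nT, spec$replicates) *
      (1 + matrix(stats::rnorm(nT * spec$replicates, 0, spec$cv), nT))
    reps_AL <- matrix(tc$AL, nT, spec$replicates) *
      (1 + matrix(stats::rnorm(nT * spec$replicates, 0, spec$cv), nT))
    reps_AP[reps_AP < 0] <- 0
    reps_AL[reps_AL < 0] <- 0
    obs[[cid]] <- data.frame(
      condition_id = cid, time_h = spec$times,
      AP = rowMeans(reps_AP), AL = rowMeans(reps_AL),
      AP_sd = apply(reps_AP, 1, stats::sd),
      AL_sd = apply(reps_AL, 1, stats::sd))
    clean[[cid]] <- tc
  }
  dataset <- flux_dataset(do.call(rbind, c(obs, make.row.names = FALSE)),
                          spec$panel, cell_line = cell_line)
  list(dataset = dataset,
       truth = list(params = spec$params, hypothesis = spec$hypothesis,
                    modifiers = spec$modifiers, trajectories = clean,
                    seed = spec$seed))
}

#' Render synthetic two-channel sensor images
#'
#' Emulates widefield frames of cells expressing the tandem sensor: cells as
#' diffuse cytoplasmic disks, autophagosomes (AP) as Gaussian spots present
#' in both the GFP and mCherry channels, autophagolysosomes (AL) as
#' mCherry-only spots (GFP quenched by the acidic lumen), with
#' Poisson-Gaussian camera noise. Spot peak amplitude is
#' `snr * sd(background noise)`.
#'
#' @param n_cells Number of cells to place.
#' @param ap_per_cell,al_per_cell True spot counts per cell.
#' @param snr Peak signal-to-noise ratio of spots over the cytoplasmic
#'   background (> 0).
#' @param seed RNG seed.
#' @param width,height Image size in pixels (default 512 x 512, 16-bit
#'   scale).
#' @param cell_radius Range of cell disk radii in pixels.
#' @param spot_sigma Gaussian spot SD in pixels (default 2).
#' @param bg_cell,bg_out Mean photon counts inside / outside cells.
#' @param read_sd Gaussian read-noise SD (counts).
#' @return List with matrices `gfp` and `mcherry` (photon counts), `truth`
#'   (data frame: cell_id, x, y, klass), `cell_labels` (true mask), and
#'   `meta` (including a `packing_warning` flag when spot placement had to
#'   give up on minimum separation).
#' @export
generate_images <- function(n_cells = 6, ap_per_cell = 10, al_per_cell = 5,
                            snr = 10, seed = 1, width = 512, height = 512,
                            cell_radius = c(40, 60), spot_sigma = 2,
                            bg_cell = 400, bg_out = 40, read_sd = 4) {
  if (ap_per_cell < 0 || al_per_cell < 0 || snr <= 0)
    stop("counts must be >= 0 and snr > 0", call. = FALSE)
  set.seed(seed)
  xs <- matrix(rep(seq_len(width), height), width)
  ys <- matrix(rep(seq_len(height), each = width), width)
  labels <- matrix(0L, width, height)
  centers <- matrix(NA_real_, n_cells, 3)
  placed <- 0
  tries <- 0
  while (placed < n_cells && tries < 2000) {
    tries <- tries + 1
    r <- stats::runif(1, cell_radius[1], cell_radius[2])
    cx <- stats::runif(1, r + 2, width - r - 2)
    cy <- stats::runif(1, r + 2, height - r - 2)
    if (placed > 0) {
      dd <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                 (centers[seq_len(placed), 2] - cy)^2)
      if (any(dd < centers[seq_len(placed), 3] + r + 6)) next
    }
    placed <- placed + 1
    centers[placed, ] <- c(cx, cy, r)
    labels[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- placed
  }
  if (placed < n_cells)
    warning("could only place ", placed, " of ", n_cells, " cells")
  n_cells <- placed
  noise_sd <- sqrt(bg_cell + read_sd^2)
  amp <- snr * noise_sd
  ideal_g <- matrix(bg_out, width, height)
  ideal_m <- matrix(bg_out, width, height)
  ideal_g[labels > 0] <- bg_cell
  ideal_m[labels > 0] <- bg_cell
  truth <- list()
  packing_warning <- FALSE
  half <- ceiling(4 * spot_sigma)
  kern_xy <- seq(-half, half)
  add_spot <- function(img, x, y) {
    ix <- round(x) + kern_xy; iy <- round(y) + kern_xy
    ok_x <- ix >= 1 & ix <= width; ok_y <- iy >= 1 & iy <= height
    g <- outer(exp(-(ix[ok_x] - x)^2 / (2 * spot_sigma^2)),
               exp(-(iy[ok_y] - y)^2 / (2 * spot_sigma^2)))
    img[ix[ok_x], iy[ok_y]] <- img[ix[ok_x], iy[ok_y]] + amp * g
    img
  }
  for (ci in seq_len(n_cells)) {
    n_spots <- ap_per_cell + al_per_cell
    pts <- matrix(NA_real_, n_spots, 2)
    got <- 0; attempts <- 0
    rmax <- centers[ci, 3] - 4 * spot_sigma - 2
    while (got < n_spots && attempts < 400 * max(1, n_spots)) {
      attempts <- attempts + 1
      a <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * rmax
      px <- centers[ci, 1] + rr * cos(a)
      py <- centers[ci, 2] + rr * sin(a)
      if (got > 0) {
        dd <- sqrt((pts[seq_len(got), 1] - px)^2 +
                   (pts[seq_len(got), 2] - py)^2)
        if (any(dd < 6 * spot_sigma)) next
      }
      got <- got + 1
      pts[got, ] <- c(px, py)
    }
    if (got < n_spots) {
      packing_warning <- TRUE
      pts <- pts[seq_len(got), , drop = FALSE]
    }
    n_ap <- min(ap_per_cell, nrow(pts))
    klass <- c(rep("AP", n_ap), rep("AL", nrow(pts) - n_ap))
    for (si in seq_len(nrow(pts))) {
      ideal_m <- add_spot(ideal_m, pts[si, 1], pts[si, 2])
      if (klass[si] == "AP")
        ideal_g <- add_spot(ideal_g, pts[si, 1], pts[si, 2])
    }
    if (nrow(pts) > 0)
      truth[[ci]] <- data.frame(cell_id = ci, x = pts[, 1], y = pts[, 2],
                                klass = klass, stringsAsFactors = FALSE)
  }
  noisify <- function(img) {
    counts <- stats::rpois(length(img), lambda = as.vector(img)) +
      stats::rnorm(length(img), 0, read_sd)
    matrix(pmin(pmax(round(counts), 0), 65535), width, height)
  }
  truth_df <- if (length(truth)) {
    do.call(rbind, c(truth, make.row.names = FALSE))
  } else {
    data.frame(cell_id = integer(), x = numeric(), y = numeric(),
               klass = character())
  }
  list(gfp = noisify(ideal_g), mcherry = noisify(ideal_m),
       truth = truth_df, cell_labels = labels,
       meta = list(n_cells = n_cells, snr = snr, amp = amp,
                   spot_sigma = spot_sigma, bg_cell = bg_cell,
                   bg_out = bg_out, read_sd = read_sd,
                   packing_warning = packing_warning, seed = seed))
}
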