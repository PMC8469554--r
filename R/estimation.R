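#' Bundle observed time courses with a perturbation design
#'
#' @param observations Data frame with columns `condition_id`, `time_h`,
#'   `AP`, `AL` and optionally `AP_sd`, `AL_sd` (replicate SDs).
#' @param design Data frame with column `condition_id` plus one 0/1 column
#'   per agent (the perturbation design matrix).
#' @param cell_line Optional label.
#' @return Object of class `flux_dataset`.
#' @export
flux_dataset <- function(observations, design, cell_line = "unknown") {
  needed <- c("condition_id", "time_h", "AP", "AL")
  if (!all(needed %in% names(observations)))
    stop("observations need columns condition_id, time_h, AP, AL",
         call. = FALSE)
  if (!"condition_id" %in% names(design))
    stop("design needs a condition_id column", call. = FALSE)
  agents <- setdiff(names(design), "condition_id")
  av <- as.matrix(design[, agents, drop = FALSE])
  if (length(av) && any(!av %in% c(0, 1)))
    stop("design activities must be coded exactly 0 or 1", call. = FALSE)
  if (!all(observations$condition_id %in% design$condition_id))
    stop("every observed condition must appear in the design", call. = FALSE)
  npts <- table(observations$condition_id)
  if (any(npts < 2))
    stop("every condition needs at least 2 time points", call. = FALSE)
  for (col in c("AP_sd", "AL_sd"))
    if (!col %in% names(observations)) observations[[col]] <- NA_real_
  structure(list(observations = observations,
                 design = design, agents = agents, cell_line = cell_line),
            class = "flux_dataset")
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat("<flux_dataset>", x$cell_line, "-",
      length(unique(x$observations$condition_id)), "conditions,",
      nrow(x$observations), "observation rows\n")
  invisible(x)
}

# Restrict a dataset to a subset of conditions.
subset_conditions <- function(dataset, keep) {
  flux_dataset(dataset$observations[dataset$observations$condition_id %in%
                                      keep, , drop = FALSE],
               dataset$design[dataset$design$condition_id %in% keep, ,
                              drop = FALSE],
               dataset$cell_line)
}

# Series-SD weights (one sigma per condition x observable): the SD of the
# observed data series, the semantics of COPASI's "standard deviation"
# weight method. Degenerate (zero / NA) sigmas are replaced by the median
# positive sigma of the dataset, or 1 if none exists.
series_weights <- function(obs) {
  conds <- unique(obs$condition_id)
  sig <- t(vapply(conds, function(cid) {
    o <- obs[obs$condition_id == cid, ]
    s <- c(stats::sd(o$AP, na.rm = TRUE), stats::sd(o$AL, na.rm = TRUE))
    # a series that is constant up to round-off carries no real SD
    lvl <- c(mean(abs(o$AP), na.rm = TRUE), mean(abs(o$AL), na.rm = TRUE))
    s[s <= 1e-8 * pmax(lvl, 1e-12)] <- NA
    s
  }, numeric(2)))
  sig[!is.finite(sig)] <- NA
  fallback <- stats::median(sig, na.rm = TRUE)
  if (!is.finite(fallback)) fallback <- 1
  sig[is.na(sig)] <- fallback
  list(conditions = conds, sd_AP = sig[, 1], sd_AL = sig[, 2])
}

# Compile a model + dataset into a fast objective. Returns:
#   fn(P)  - P a matrix (particles x parameters) -> vector of weighted SSE
#   fn1(p) - scalar version
# Requires all conditions to share one sampling grid (the kinetic assay's
# 3 h grid); initial state is the basal steady state of the candidate rates.
compile_objective <- function(model, dataset) {
  obs <- dataset$observations
  obs <- obs[order(match(obs$condition_id, unique(obs$condition_id)),
                   obs$time_h), ]
  w <- series_weights(obs)
  conds <- w$conditions
  times <- sort(unique(obs$time_h))
  nc <- length(conds)
  nt <- length(times)
  if (nrow(obs) != nc * nt ||
      !all(obs$time_h == rep(times, times = nc)))
    stop("all conditions must share one common time grid", call. = FALSE)
  Y_AP <- matrix(obs$AP, nrow = nc, ncol = nt, byrow = TRUE)
  Y_AL <- matrix(obs$AL, nrow = nc, ncol = nt, byrow = TRUE)
  w_AP <- 1 / w$sd_AP^2
  w_AL <- 1 / w$sd_AL^2
  # signed activity matrices (condition x strength parameter)
  mods <- model$modifiers
  ns <- nrow(mods)
  has_scales <- "scale_AP" %in% model$par_names
  des <- dataset$design[match(conds, dataset$design$condition_id), ,
                        drop = FALSE]
  act_of <- function(agent) {
    if (agent %in% names(des)) as.numeric(des[[agent]]) else numeric(nc)
  }
  sign_of <- ifelse(mods$direction == "activate", 1, -1)
  A <- matrix(0, nrow = nc, ncol = ns)
  for (j in seq_len(ns)) A[, j] <- act_of(mods$agent[j]) * sign_of[j]
  M_form <- A * rep(as.numeric(mods$target == "formation"), each = nc)
  M_conv <- A * rep(as.numeric(mods$target == "conversion"), each = nc)
  M_deg  <- A * rep(as.numeric(mods$target == "degradation"), each = nc)
  fin_AP <- is.finite(Y_AP); Y_AP[!fin_AP] <- 0
  fin_AL <- is.finite(Y_AL); Y_AL[!fin_AL] <- 0

  # expanded copies of the observation blocks are reused across the many
  # same-sized swarm evaluations of one PSO run
  cache <- new.env(parent = emptyenv())
  expand_for <- function(np) {
    key <- as.character(np)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cid <- rep(seq_len(nc), each = np)
    e <- list(cid = cid,
              Yap = Y_AP[cid, , drop = FALSE],
              Yal = Y_AL[cid, , drop = FALSE],
              fap = !fin_AP[cid, , drop = FALSE],
              fal = !fin_AL[cid, , drop = FALSE],
              wap = w_AP[cid], wal = w_AL[cid],
              grp = rep(seq_len(np), times = nc))
    cache[[key]] <- e
    e
  }

  fn <- function(P) {
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    np <- nrow(P)
    kf <- P[, 1]; kc <- P[, 2]; kd <- P[, 3]
    if (ns > 0) {
      L <- log1p(P[, 3 + seq_len(ns), drop = FALSE])
      Fm <- kf * exp(tcrossprod(L, M_form))
      Cm <- kc * exp(tcrossprod(L, M_conv))
      Dm <- kd * exp(tcrossprod(L, M_deg))
    } else {
      Fm <- matrix(kf, np, nc); Cm <- matrix(kc, np, nc)
      Dm <- matrix(kd, np, nc)
    }
    # rows: particle fastest, condition slowest
    ap0 <- ifelse(kf > 0, kf / kc, 0)
    al0 <- ifelse(kf > 0, kf / kd, 0)
    tr <- flux_traj_core(as.vector(Fm), as.vector(Cm), as.vector(Dm),
                         rep(ap0, nc), rep(al0, nc),
                         numeric(np * nc), times)
    e <- expand_for(np)
    if (has_scales) {
      sAP <- rep(P[, 3 + ns + 1], nc)
      sAL <- rep(P[, 3 + ns + 2], nc)
      rAP <- tr$AP * sAP - e$Yap
      rAL <- tr$AL * sAL - e$Yal
    } else {
      rAP <- tr$AP - e$Yap
      rAL <- tr$AL - e$Yal
    }
    if (any(e$fap)) rAP[e$fap] <- 0
    if (any(e$fal)) rAL[e$fal] <- 0
    sse_rows <- rowSums(rAP * rAP) * e$wap + rowSums(rAL * rAL) * e$wal
    out <- rowsum(sse_rows, group = e$grp)[, 1]
    out[!is.finite(out)] <- Inf
    unname(out)
  }
  list(fn = fn, fn1 = function(p) fn(matrix(p, nrow = 1))[1],
       conditions = conds, times = times,
       sd_AP = w$sd_AP, sd_AL = w$sd_AL)
}

#' Weighted least-squares objective of a candidate model
#'
#' The fit criterion: `sum over conditions, times and observables of
#' w * (y - yhat)^2` with `w = 1/sigma^2`, where `sigma` is the observable's
#' SD within the condition's data series (standard-deviation weighting).
#' Simulations start from the basal steady state of the candidate rates.
#'
#' @param par Named parameter vector matching `model$par_names`.
#' @param model A [build_model()] skeleton.
#' @param dataset A [flux_dataset()].
#' @return Non-negative scalar; `Inf` if the simulation is not finite.
#' @export
flux_objective <- function(par, model, dataset) {
  par <- par[model$par_names]
  compile_objective(model, dataset)$fn1(par)
}

#' Particle swarm optimisation
#'
#' Global-best PSO with constriction-style coefficients: inertia 0.729,
#' cognitive = social = 1.49445, velocities clamped to a fraction of the box
#' range, positions clamped to bounds. Terminates when the swarm's objective
#' standard deviation falls below `stop_sd` or at `max_iter`. Fully
#' reproducible given `seed`.
#'
#' @param fn Objective. With `vectorized = TRUE` it must accept a matrix
#'   (particles in rows) and return a vector.
#' @param lower,upper Finite bounds, `lower < upper` per dimension.
#' @param control List from [pso_control()].
#' @param vectorized Whether `fn` evaluates a whole swarm at once.
#' @return List with `par`, `value`, `iterations`, `converged`, and `trace`
#'   (per-iteration best value and swarm SD).
#' @examples
#' sph <- function(x) sum(x^2)
#' r <- pso_minimize(sph, rep(-5, 3), rep(5, 3),
#'                   control = pso_control(seed = 1))
#' r$value < 1e-6
#' @export
pso_minimize <- function(fn, lower, upper, control = pso_control(),
                         vectorized = FALSE) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  n <- control$swarm_size
  set.seed(control$seed)
  init <- control$init
  if (init == "auto") init <- if (all(lower > 0)) "loguniform" else "uniform"
  X <- if (init == "loguniform") {
    exp(matrix(stats::runif(n * d, rep(log(lower), each = n),
                            rep(log(upper), each = n)), n, d))
  } else {
    matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
           n, d)
  }
  V <- matrix(0, n, d)
  vmax <- control$vmax_frac * (upper - lower)
  evalf <- if (vectorized) fn else function(M) apply(M, 1, fn)
  f <- evalf(X)
  if (all(!is.finite(f)))
    stop("objective non-finite over the entire initial swarm", call. = FALSE)
  pbest <- X; pf <- f
  g <- which.min(pf)
  trace <- matrix(NA_real_, control$max_iter + 1, 2,
                  dimnames = list(NULL, c("best", "swarm_sd")))
  trace[1, ] <- c(pf[g], stats::sd(f))
  iter <- 0
  converged <- stats::sd(f) < control$stop_sd
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1
    r1 <- matrix(stats::runif(n * d), n, d)
    r2 <- matrix(stats::runif(n * d), n, d)
    V <- control$inertia * V +
      control$c_cog * r1 * (pbest - X) +
      control$c_soc * r2 * sweep(X, 2, pbest[g, ], function(x, gb) gb - x)
    V <- pmin(pmax(V, rep(-vmax, each = n)), rep(vmax, each = n))
    X <- X + V
    lowm <- rep(lower, each = n); uppm <- rep(upper, each = n)
    outb <- X < lowm | X > uppm
    X <- pmin(pmax(X, lowm), uppm)
    V[outb] <- 0
    f <- evalf(X)
    better <- is.finite(f) & f < pf
    pbest[better, ] <- X[better, , drop = FALSE]
    pf[better] <- f[better]
    g <- which.min(pf)
    sdv <- stats::sd(f)
    trace[iter + 1, ] <- c(pf[g], sdv)
    converged <- is.finite(sdv) && sdv < control$stop_sd
  }
  list(par = pbest[g, ], value = pf[g], iterations = iter,
       converged = converged,
       trace = as.data.frame(trace[seq_len(iter + 1), , drop = FALSE]))
}

#' PSO configuration
#'
#' Defaults follow the estimation setup of the study design: swarm size 50,
#' iteration limit 2000 and a stopping standard deviation of 1e-6, with
#' standard constriction coefficients.
#'
#' @param swarm_size Number of particles.
#' @param max_iter Iteration limit.
#' @param stop_sd Terminate when the swarm objective SD drops below this.
#' @param seed RNG seed (every stochastic call requires one).
#' @param inertia,c_cog,c_soc PSO coefficients.
#' @param vmax_frac Velocity clamp as a fraction of each box range.
#' @param init "auto" (log-uniform when all bounds positive), "uniform" or
#'   "loguniform".
#' @return Control list.
#' @export
pso_control <- function(swarm_size = 50, max_iter = 2000, stop_sd = 1e-6,
                        seed = 1, inertia = 0.729, c_cog = 1.49445,
                        c_soc = 1.49445, vmax_frac = 0.2,
                        init = c("auto", "uniform", "loguniform")) {
  list(swarm_size = swarm_size, max_iter = max_iter, stop_sd = stop_sd,
       seed = seed, inertia = inertia, c_cog = c_cog, c_soc = c_soc,
       vmax_frac = vmax_frac, init = match.arg(init))
}

#' Fit one candidate model to a dataset
#'
#' Minimises [flux_objective()] by [pso_minimize()] (optionally multi-start)
#' followed by a bounded local polish (`nlminb`). Parameters listed in
#' `fixed` are held constant and removed from the search space (used by the
#' two-stage strategy).
#'
#' @param model A [build_model()] skeleton.
#' @param dataset A [flux_dataset()].
#' @param control [pso_control()] settings; `control$seed` seeds the fit.
#' @param polish Run a local bounded refinement after PSO (default TRUE).
#' @param n_starts Independent PSO starts (seeds `seed`, `seed+1`, ...).
#' @param fixed Optional named numeric of parameters to freeze.
#' @return Object of class `flux_fit`: `hypothesis_id`, `par` (full named
#'   vector), `objective`, `n_free`, `converged`, `seed`, `iterations`.
#' @export
fit_flux <- function(model, dataset, control = pso_control(), polish = TRUE,
                     n_starts = 1, fixed = NULL) {
  obj <- compile_objective(model, dataset)
  free <- setdiff(model$par_names, names(fixed))
  full <- stats::setNames(numeric(length(model$par_names)), model$par_names)
  if (!is.null(fixed)) full[names(fixed)] <- fixed
  embed <- function(P) {
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    M <- matrix(rep(full, each = nrow(P)), nrow(P),
                length(full), dimnames = list(NULL, names(full)))
    M[, free] <- P
    M
  }
  fnv <- function(P) obj$fn(embed(P))
  fn1 <- function(p) fnv(matrix(p, nrow = 1))[1]
  if (length(free) == 0) {
    val <- obj$fn1(full)
    return(structure(list(hypothesis_id = model$hypothesis_id, par = full,
                          objective = val, n_free = 0, converged = TRUE,
                          seed = control$seed, iterations = 0),
                     class = "flux_fit"))
  }
  lower <- model$lower[free]; upper <- model$upper[free]
  # rates and strengths span decades: search in log coordinates
  log_scale <- all(lower > 0)
  if (log_scale) {
    fnv_s <- function(P) fnv(exp(P)); fn1_s <- function(p) fn1(exp(p))
    lo <- log(lower); up <- log(upper)
  } else {
    fnv_s <- fnv; fn1_s <- fn1; lo <- lower; up <- upper
  }
  best <- NULL; best_r <- NULL
  for (k in seq_len(n_starts)) {
    ctl <- control; ctl$seed <- control$seed + k - 1
    ctl$init <- "uniform"
    r <- pso_minimize(fnv_s, lo, up, control = ctl, vectorized = TRUE)
    par_k <- r$par; val_k <- r$value
    if (polish) {
      pol <- try(stats::nlminb(par_k, fn1_s, lower = lo, upper = up,
                               control = list(iter.max = 500)),
                 silent = TRUE)
      if (!inherits(pol, "try-error") && is.finite(pol$objective) &&
          pol$objective <= val_k) {
        par_k <- pmin(pmax(pol$par, lo), up)
        val_k <- fn1_s(par_k)
      }
    }
    if (is.null(best) || val_k < best$value) {
      best <- list(par = par_k, value = val_k)
      best_r <- r
    }
  }
  par <- best$par; val <- best$value
  full[free] <- if (log_scale) exp(par) else par
  structure(list(hypothesis_id = model$hypothesis_id, par = full,
                 objective = val, n_free = length(free),
                 converged = best_r$converged, seed = control$seed,
                 iterations = best_r$iterations),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit>", x$hypothesis_id, " objective:",
      format(x$objective, digits = 6), " free:", x$n_free, "\n")
  invisible(x)
}

#' Fit and score a whole hypothesis family
#'
#' Two fitting strategies:
#' \describe{
#'   \item{two_stage (default)}{Stage 1 estimates basal rates and library
#'     strengths on the drug-free conditions; stage 2 freezes them and fits
#'     only each hypothesis' drug strengths on the drug-containing
#'     conditions. Each fit's reported objective is then the full-dataset
#'     objective at the combined parameters, so hypotheses (including
#'     all-none) are ranked on a common scale.}
#'   \item{joint}{All parameters of every family member are fitted jointly
#'     on the full dataset.}
#' }
#'
#' @param dataset A [flux_dataset()].
#' @param drugs Drugs with unknown mode of action (must be design columns).
#' @param library Known-agent assignments; defaults to [agent_library()]
#'   restricted to agents present in the design.
#' @param hypotheses Optional pre-built family; defaults to
#'   [enumerate_hypotheses()] over `drugs`.
#' @param strategy "two_stage" or "joint".
#' @param control,polish,n_starts Passed to [fit_flux()].
#' @param stage1_starts Independent starts for the shared stage-1 fit (the
#'   basal + library estimate every hypothesis inherits); its landscape is
#'   multimodal, so a few restarts buy reliability cheaply.
#' @return List of `flux_fit` objects (one per hypothesis).
#' @export
fit_hypotheses <- function(dataset, drugs, library = NULL, hypotheses = NULL,
                           strategy = c("two_stage", "joint"),
                           control = pso_control(), polish = TRUE,
                           n_starts = 1, stage1_starts = 3) {
  strategy <- match.arg(strategy)
  if (is.null(library)) library <- agent_library()
  # only agents actually perturbed in this design are identifiable
  present <- intersect(unique(library$agent), dataset$agents)
  active <- present[vapply(present, function(a)
    any(dataset$design[[a]] == 1), logical(1))]
  library <- library[library$agent %in% active, , drop = FALSE]
  if (is.null(hypotheses)) hypotheses <- enumerate_hypotheses(drugs)
  drug_active <- rep(FALSE, nrow(dataset$design))
  for (d in drugs) {
    if (!d %in% dataset$agents)
      stop("drug not in design: ", d, call. = FALSE)
    drug_active <- drug_active | dataset$design[[d]] == 1
  }
  if (strategy == "joint") {
    return(lapply(hypotheses, function(h) {
      fit_flux(build_model(h, library), dataset, control = control,
               polish = polish, n_starts = n_starts)
    }))
  }
  base_conds <- dataset$design$condition_id[!drug_active]
  chemo_conds <- dataset$design$condition_id[drug_active]
  if (length(base_conds) == 0 || length(chemo_conds) == 0)
    stop("two-stage fitting needs both drug-free and drug-containing ",
         "conditions", call. = FALSE)
  h_none <- mode_hypothesis(stats::setNames(rep("none", length(drugs)), drugs))
  base_model <- build_model(h_none, library)
  base_fit <- fit_flux(base_model, subset_conditions(dataset, base_conds),
                       control = control, polish = polish,
                       n_starts = max(n_starts, stage1_starts))
  stage1 <- base_fit$par
  chemo_data <- subset_conditions(dataset, chemo_conds)
  lapply(hypotheses, function(h) {
    model <- build_model(h, library)
    fixed <- stage1[intersect(names(stage1), model$par_names)]
    fit <- fit_flux(model, chemo_data, control = control, polish = polish,
                    n_starts = n_starts, fixed = fixed)
    # report the full-dataset objective at the combined parameters
    fit$objective <- compile_objective(model, dataset)$fn1(fit$par)
    fit
  })
}

#' Rank fitted hypotheses by objective value
#'
#' Ascending objective; ties within `tie_tol` broken by fewer free
#' parameters (parsimony), then lexicographic hypothesis id.
#'
#' @param fits List of `flux_fit` objects for one dataset.
#' @param tie_tol Absolute objective tie tolerance.
#' @return Object of class `flux_ranking`: data frame `table` (rank,
#'   hypothesis_id, objective, n_free), `best` fit, and `best_modes`
#'   (per-drug mode summary).
#' @export
rank_models <- function(fits, tie_tol = 1e-6) {
  if (length(fits) == 0) stop("no fits to rank", call. = FALSE)
  obj <- vapply(fits, function(f) f$objective, numeric(1))
  nf <- vapply(fits, function(f) f$n_free, numeric(1))
  id <- vapply(fits, function(f) f$hypothesis_id, character(1))
  # quantise objectives to the tie tolerance so near-equal values compare
  # by parsimony, then id
  ord <- order(round(obj / tie_tol), nf, id)
  best <- fits[[ord[1]]]
  modes <- strsplit(best$hypothesis_id, "|", fixed = TRUE)[[1]]
  kv <- strsplit(modes, ":", fixed = TRUE)
  best_modes <- stats::setNames(vapply(kv, `[`, character(1), 2),
                                vapply(kv, `[`, character(1), 1))
  structure(list(table = data.frame(rank = seq_along(ord),
                                    hypothesis_id = id[ord],
                                    objective = obj[ord], n_free = nf[ord]),
                 fits = fits[ord], best = best, best_modes = best_modes),
            class = "flux_ranking")
}

#' @export
print.flux_ranking <- function(x, ...) {
  cat("<flux_ranking> best:", x$best$hypothesis_id, "\n")
  print(utils::head(x$table, 5))
  invisible(x)
}
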