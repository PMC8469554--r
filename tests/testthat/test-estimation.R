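test_that("objective matches an independent per-condition computation", {
  gen <- make_recovery("deg-", cv = 0.1, seed = 21)
  ds <- gen$dataset
  lib <- agent_library()
  lib <- lib[lib$agent %in% c("STV", "BAF"), ]
  model <- build_model(mode_hypothesis(c(EPI = "deg-")), lib)
  par <- c(k_form = 8, k_conv = 1.2, k_deg = 1.7, s_STV_form = 3,
           s_STV_conv = 5, s_BAF_conv = 2, s_EPI_deg = 4)

  # oracle: loop conditions with simulate_flux and accumulate w * res^2,
  # sigma being each observable's SD within the condition's series
  mods <- modifier_table(model$modifiers$agent, model$modifiers$target,
                         model$modifiers$direction,
                         unname(par[model$modifiers$param]))
  p0 <- flux_params(par[["k_form"]], par[["k_conv"]], par[["k_deg"]])
  init <- basal_steady_init(p0)
  expected <- 0
  sds <- c()
  for (cid in unique(ds$observations$condition_id)) {
    o <- ds$observations[ds$observations$condition_id == cid, ]
    sds <- c(sds, sd(o$AP), sd(o$AL))
  }
  for (cid in unique(ds$observations$condition_id)) {
    o <- ds$observations[ds$observations$condition_id == cid, ]
    act <- ds$design[ds$design$condition_id == cid, ds$agents]
    tc <- simulate_flux(p0, mods, stats::setNames(as.numeric(act), ds$agents),
                        init = init, times = o$time_h)
    for (obsv in c("AP", "AL")) {
      sig <- sd(o[[obsv]])
      if (!is.finite(sig) || sig <= 1e-8 * mean(abs(o[[obsv]])))
        sig <- median(sds, na.rm = TRUE)
      expected <- expected + sum((o[[obsv]] - tc[[obsv]])^2) / sig^2
    }
  }
  expect_equal(flux_objective(par, model, ds), expected, tolerance = 1e-10)
})

test_that("objective is invariant to a joint rescaling of data and k_form", {
  # the chain is linear in k_form and sigma is the series SD, so scaling all
  # observations by c together with k_form leaves every w * res^2 unchanged
  # (the 1/sigma^2 weighting at work)
  gen <- make_recovery("form+", cv = 0.1, seed = 8)
  ds <- gen$dataset
  lib <- agent_library()
  lib <- lib[lib$agent %in% c("STV", "BAF"), ]
  model <- build_model(mode_hypothesis(c(EPI = "form+")), lib)
  par <- c(k_form = 10, k_conv = 1, k_deg = 2, s_STV_form = 4,
           s_STV_conv = 4, s_BAF_conv = 4, s_EPI_form = 5)
  v1 <- flux_objective(par, model, ds)
  ds2 <- ds
  ds2$observations$AP <- ds$observations$AP * 3
  ds2$observations$AL <- ds$observations$AL * 3
  par2 <- par; par2[["k_form"]] <- par[["k_form"]] * 3
  v2 <- flux_objective(par2, model, ds2)
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("objective on noise-free data at the generating parameters is ~0", {
  gen <- make_recovery("conv-", cv = 0, seed = 2)
  lib <- agent_library()
  lib <- lib[lib$agent %in% c("STV", "BAF"), ]
  model <- build_model(mode_hypothesis(c(EPI = "conv-")), lib)
  par <- c(k_form = 10, k_conv = 1, k_deg = 2, s_STV_form = 4,
           s_STV_conv = 4, s_BAF_conv = 4, s_EPI_conv = 5)
  expect_lt(flux_objective(par, model, gen$dataset), 1e-8)
})

test_that("PSO solves standard benchmarks at the reference settings", {
  sphere <- function(x) sum(x^2)
  r <- pso_minimize(sphere, rep(-5, 3), rep(5, 3),
                    control = pso_control(seed = 42))
  expect_lt(r$value, 1e-6)

  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r2 <- pso_minimize(rosen, c(-2, -2), c(2, 2),
                     control = pso_control(seed = 42))
  expect_lt(r2$value, 1e-3)
})

test_that("PSO is bit-reproducible and respects bounds at every evaluation", {
  lower <- c(-3, -3); upper <- c(3, 3)
  seen_out <- FALSE
  watched <- function(x) {
    if (any(x < lower - 1e-12) || any(x > upper + 1e-12)) seen_out <<- TRUE
    sum((x - 1)^2)
  }
  a <- pso_minimize(watched, lower, upper, control = pso_control(seed = 7))
  b <- pso_minimize(watched, lower, upper, control = pso_control(seed = 7))
  expect_false(seen_out)
  expect_identical(a$par, b$par)
  expect_identical(a$value, b$value)
  expect_identical(a$trace, b$trace)

  expect_error(pso_minimize(function(x) Inf, 0, 1,
                            control = pso_control(seed = 1)),
               "initial swarm")
  expect_error(pso_minimize(function(x) sum(x), c(0, 1), c(1, 0),
                            control = pso_control(seed = 1)),
               "bounds")
})

test_that("noise-free fit recovers the generating rates within 5%", {
  gen <- make_recovery("deg-", cv = 0, seed = 3)
  lib <- agent_library()
  lib <- lib[lib$agent %in% c("STV", "BAF"), ]
  model <- build_model(mode_hypothesis(c(EPI = "deg-")), lib)
  fit <- fit_flux(model, gen$dataset, control = pso_control(seed = 3),
                  n_starts = 3)
  truth <- c(k_form = 10, k_conv = 1, k_deg = 2)
  rel <- abs(fit$par[names(truth)] - truth) / truth
  expect_true(all(rel < 0.05))
  expect_lt(fit$objective, 1e-8)
})

test_that("all-zero observations drive formation to its lower bound", {
  obs <- expand.grid(time_h = seq(0, 12, 3), condition_id = c("a", "b"))
  obs$AP <- 0; obs$AL <- 0
  design <- data.frame(condition_id = c("a", "b"))
  ds <- flux_dataset(obs[, c("condition_id", "time_h", "AP", "AL")], design)
  model <- build_model(mode_hypothesis(c(EPI = "none")),
                       modifier_table())
  model$lower[] <- c(0, 0.1, 0.1)
  model$upper[] <- c(10, 10, 10)
  fit <- fit_flux(model, ds, control = pso_control(seed = 1))
  expect_lt(fit$par[["k_form"]], 1e-6)
  expect_lt(fit$objective, 1e-10)
})

test_that("fitting is deterministic given a seed", {
  gen <- make_recovery("form-", cv = 0.1, seed = 5)
  f1 <- fit_hypotheses(gen$dataset, "EPI", control = pso_control(seed = 5))
  f2 <- fit_hypotheses(gen$dataset, "EPI", control = pso_control(seed = 5))
  expect_identical(lapply(f1, function(f) f$par),
                   lapply(f2, function(f) f$par))
  expect_identical(vapply(f1, function(f) f$objective, numeric(1)),
                   vapply(f2, function(f) f$objective, numeric(1)))
})

test_that("ranking orders by objective with a parsimony tie-break", {
  mk <- function(id, obj, nf) structure(
    list(hypothesis_id = id, par = numeric(), objective = obj, n_free = nf,
         converged = TRUE, seed = 1, iterations = 0), class = "flux_fit")
  rk <- rank_models(list(mk("A:none", 5, 3), mk("B:none", 1, 4),
                         mk("C:none", 3, 2)))
  expect_equal(rk$table$hypothesis_id, c("B:none", "C:none", "A:none"))

  rk2 <- rank_models(list(mk("big:none", 2, 12), mk("small:none", 2, 11)))
  expect_equal(rk2$table$hypothesis_id[1], "small:none")

  rk3 <- rank_models(list(mk("b:none", 2, 3), mk("a:none", 2, 3)))
  expect_equal(rk3$table$hypothesis_id[1], "a:none")

  expect_error(rank_models(list()), "no fits")
})

test_that("fitted observation scales absorb a units change in the data", {
  gen <- make_recovery("deg-", cv = 0, seed = 12)
  ds <- gen$dataset
  ds$observations$AP <- ds$observations$AP * 2.5
  ds$observations$AL <- ds$observations$AL * 0.4
  lib <- agent_library()
  lib <- lib[lib$agent %in% c("STV", "BAF"), ]
  model <- build_model(mode_hypothesis(c(EPI = "deg-")), lib,
                       fit_scales = TRUE)
  expect_true(all(c("scale_AP", "scale_AL") %in% model$par_names))
  # kinetics fixed at truth: the scales alone must absorb the units change
  fixed <- c(k_form = 10, k_conv = 1, k_deg = 2, s_STV_form = 4,
             s_STV_conv = 4, s_BAF_conv = 4, s_EPI_deg = 5)
  fit <- fit_flux(model, ds, control = pso_control(seed = 12), fixed = fixed)
  expect_equal(fit$par[["scale_AP"]], 2.5, tolerance = 1e-4)
  expect_equal(fit$par[["scale_AL"]], 0.4, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-8)
})

test_that("two-stage and joint strategies agree on an easy truth", {
  gen <- make_recovery("deg+", cv = 0, seed = 9)
  hyps <- lapply(c("deg+", "none"), function(m)
    mode_hypothesis(stats::setNames(m, "EPI")))
  two <- rank_models(fit_hypotheses(gen$dataset, "EPI", hypotheses = hyps,
                                    control = pso_control(seed = 2)))
  joint <- rank_models(fit_hypotheses(gen$dataset, "EPI", hypotheses = hyps,
                                      strategy = "joint",
                                      control = pso_control(seed = 2),
                                      n_starts = 2))
  expect_equal(two$best$hypothesis_id, "EPI:deg+")
  expect_equal(joint$best$hypothesis_id, "EPI:deg+")
})
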