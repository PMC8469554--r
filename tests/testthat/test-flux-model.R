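test_that("effective rates apply the multiplicative modifier law", {
  p <- flux_params(2, 1, 1)
  expect_equal(effective_rates(p), c(r_form = 2, r_conv = 1, r_deg = 1))

  m <- modifier_table("BAF", "conversion", "inhibit", 9)
  r <- effective_rates(flux_params(1, 1, 1), m, c(BAF = 1))
  expect_equal(r[["r_conv"]], 0.1)
  # inactive agent is a no-op, as is an agent absent from the activity vector
  expect_equal(effective_rates(flux_params(1, 1, 1), m, c(BAF = 0)),
               effective_rates(flux_params(1, 1, 1), m, NULL))

  # opposing equal-strength effects on the same reaction cancel exactly
  m2 <- modifier_table(c("STV", "WRT"), c("formation", "formation"),
                       c("activate", "inhibit"), c(3, 3))
  r2 <- effective_rates(flux_params(1, 1, 1), m2, c(STV = 1, WRT = 1))
  expect_equal(r2[["r_form"]], 1)

  # composition across agents is a product
  m3 <- modifier_table(c("A", "B"), c("degradation", "degradation"),
                       c("activate", "activate"), c(1, 2))
  r3 <- effective_rates(flux_params(1, 1, 5), m3, c(A = 1, B = 1))
  expect_equal(r3[["r_deg"]], 5 * 2 * 3)
})

test_that("invalid modifiers and activities are rejected", {
  expect_error(modifier_table("X", "conversion", "inhibit", -1), "strength")
  expect_error(modifier_table(c("X", "X"), c("formation", "formation"),
                              c("activate", "inhibit"), c(1, 1)),
               "one modifier per reaction")
  m <- modifier_table("X", "formation", "activate", 1)
  expect_error(effective_rates(flux_params(1, 1, 1), m, c(X = 0.5)),
               "0 or 1")
  expect_error(flux_params(-1, 1, 1), "finite")
})

test_that("simulation matches closed forms: empty system, blockade, steady state", {
  # empty system stays at zero
  z <- simulate_flux(flux_params(0, 1, 1), init = c(AP = 0, AL = 0, SINK = 0),
                     times = c(0, 5, 10))
  expect_true(all(z$AP == 0 & z$AL == 0 & z$SINK == 0))

  # full conversion blockade: AP grows linearly at k_form
  tc <- simulate_flux(flux_params(5, 0, 1), init = c(AP = 0, AL = 0, SINK = 0),
                      times = seq(0, 12, 3))
  expect_equal(tc$AP, 5 * tc$time_h, tolerance = 1e-12)

  # long-run state reaches the analytic steady state
  p <- flux_params(10, 1, 2)
  tc <- simulate_flux(p, times = seq(0, 100, 25),
                      init = c(AP = 0, AL = 0, SINK = 0))
  expect_equal(tail(tc$AP, 1), 10, tolerance = 1e-8)
  expect_equal(tail(tc$AL, 1), 5, tolerance = 1e-8)
})

test_that("analytic and lsoda routes agree under perturbations", {
  m <- modifier_table(c("BAF", "STV", "STV"),
                      c("conversion", "formation", "conversion"),
                      c("inhibit", "activate", "activate"), c(4, 4, 4))
  for (p in random_params(5, seed = 11)) {
    t1 <- simulate_flux(p, m, c(BAF = 1, STV = 1), times = seq(0, 12, 3))
    t2 <- simulate_flux(p, m, c(BAF = 1, STV = 1), times = seq(0, 12, 3),
                        method = "lsoda")
    expect_equal(t1$AP, t2$AP, tolerance = 1e-6)
    expect_equal(t1$AL, t2$AL, tolerance = 1e-6)
    expect_equal(t1$SINK, t2$SINK, tolerance = 1e-6)
  }
})

test_that("mass balance: total material grows exactly at the formation rate", {
  for (p in random_params(10, seed = 3)) {
    tc <- simulate_flux(p, times = seq(0, 24, 2))
    r <- attr(tc, "rates")
    total0 <- tc$AP[1] + tc$AL[1] + tc$SINK[1]
    gain <- tc$AP + tc$AL + tc$SINK - total0
    expect_equal(gain, r[["r_form"]] * tc$time_h,
                 tolerance = 1e-6)
  }
})

test_that("stronger conversion inhibition never decreases AP", {
  p <- flux_params(10, 1, 2)
  times <- seq(0, 12, 0.5)
  prev <- simulate_flux(p, times = times)$AP
  for (s in c(0.5, 2, 8, 32)) {
    m <- modifier_table("BAF", "conversion", "inhibit", s)
    cur <- simulate_flux(p, m, c(BAF = 1), times = times)$AP
    expect_true(all(cur >= prev - 1e-9))
    prev <- cur
  }
})

test_that("full conversion blockade reproduces the bafilomycin phenotype", {
  # from the basal steady state, blocking conversion makes AP rise
  # monotonically while AL decays toward zero
  p <- flux_params(10, 1, 2)
  init <- basal_steady_init(p)
  tc <- simulate_flux(flux_params(10, 0, 2), init = init,
                      times = seq(0, 24, 1))
  expect_true(all(diff(tc$AP) > 0))
  expect_true(all(diff(tc$AL) < 0))
  expect_lt(tail(tc$AL, 1), 1e-3 * init[["AL"]] + 1e-6)
})

test_that("steady_state closed form and its algebra", {
  p <- flux_params(10, 1, 2)
  ss <- steady_state(p)
  expect_equal(unname(ss), c(10, 5, 0.5))
  expect_error(steady_state(flux_params(1, 0, 1)), "no steady state")
  expect_error(steady_state(flux_params(0, 1, 1)), "0/0")

  # doubling r_conv halves AP*, leaves AL*, doubles the ratio
  p2 <- flux_params(10, 2, 2)
  ss2 <- steady_state(p2)
  expect_equal(ss2[["AP"]], ss[["AP"]] / 2)
  expect_equal(ss2[["AL"]], ss[["AL"]])
  expect_equal(ss2[["ratio"]], ss[["ratio"]] * 2)
})

test_that("al_ap_ratio flags degenerate points instead of dividing", {
  tc <- data.frame(AP = c(10, 10, 0), AL = c(5, 20, 7))
  expect_equal(al_ap_ratio(tc), c(0.5, 2, NA))
  expect_error(al_ap_ratio(data.frame(AP = numeric(), AL = numeric())),
               "empty")

  # along a trajectory the ratio converges to r_conv / r_deg
  p <- flux_params(10, 1, 2)
  tc <- simulate_flux(p, times = c(0, 50, 100),
                      init = c(AP = 1, AL = 1, SINK = 0))
  expect_equal(tail(al_ap_ratio(tc), 1), steady_state(p)[["ratio"]],
               tolerance = 1e-8)
})

test_that("simulation guards bad inputs", {
  p <- flux_params(1, 1, 1)
  expect_error(simulate_flux(p, times = c(3, 2)), "strictly increasing")
  expect_error(simulate_flux(p, times = c(-1, 2)), "strictly increasing|non-negative")
  expect_error(simulate_flux(p, init = c(AP = -1, AL = 0, SINK = 0),
                             times = c(0, 1)), "non-negative")
})
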