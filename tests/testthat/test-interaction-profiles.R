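test_that("live fraction follows the PI-negative / total rule", {
  expect_equal(live_fraction(100, 25), 0.75)
  expect_equal(live_fraction(50, 0), 1)
  expect_equal(live_fraction(80, 80), 0)
  expect_error(live_fraction(0, 0), "n_total = 0")
  expect_error(live_fraction(10, 11), "n_dead")
})

test_that("Bliss score separates synergism, independence and antagonism", {
  ind <- interaction_score(0.5, 0.5, 0.25)
  expect_equal(ind$score, 0)
  expect_equal(ind$classification, "none")

  syn <- interaction_score(0.5, 1.0, 0.2)
  expect_equal(syn$expected, 0.5)
  expect_equal(syn$score, 0.3)
  expect_equal(syn$classification, "synergism")

  ant <- interaction_score(0.6, 0.9, 0.9)
  expect_equal(ant$score, -0.36)
  expect_equal(ant$classification, "antagonism")

  expect_error(interaction_score(1.2, 0.5, 0.5), "\\[0, 1\\]")

  # bounded in [-1, 1] over random valid inputs
  set.seed(1)
  for (i in 1:50) {
    v <- runif(3)
    s <- interaction_score(v[1], v[2], v[3])$score
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("fold change normalises to the untreated control", {
  expect_equal(fold_change(500, 200), 2.5)
  expect_equal(fold_change(200, 200), 1)
  expect_equal(fold_change(0, 200), 0)
  expect_error(fold_change(10, 0), "> 0")
})

test_that("ATP calibration inverts the standard curve", {
  std <- data.frame(conc_uM = c(1, 5, 100, 250, 500, 1000))
  std$signal <- 2 * std$conc_uM            # slope 2, intercept 0
  out <- atp_concentration(c(500, 2000), std)
  expect_equal(out$conc_uM, c(250, 1000), tolerance = 1e-10)
  expect_false(out$extrapolated[1])
  expect_true(atp_concentration(3000, std)$extrapolated)

  # noisy standards still recover concentrations within 15%
  set.seed(2)
  std_n <- std
  std_n$signal <- std$signal * (1 + rnorm(6, 0, 0.05))
  rec <- atp_concentration(2 * c(100, 250, 500), std_n)
  expect_true(all(abs(rec$conc_uM - c(100, 250, 500)) /
                    c(100, 250, 500) < 0.15))

  expect_error(atp_concentration(1, data.frame(conc_uM = c(1, 1),
                                               signal = c(5, 5))),
               "distinct")
  expect_error(atp_concentration(1, data.frame(conc_uM = c(1, 100),
                                               signal = c(7, 7))),
               "degenerate")
})

make_viability <- function() {
  chemo <- c("EPI", "CIS", "PAC"); mods <- c("RAP", "TOR", "WRT", "SPA", "HCQ")
  conds <- c(chemo, mods, as.vector(outer(chemo, mods, paste, sep = "+")))
  set.seed(3)
  do.call(rbind, lapply(conds, function(cid) {
    data.frame(condition_id = cid, n_total = 200,
               n_dead = rbinom(3, 200, 0.3))
  }))
}

test_that("heatmap table has one Bliss cell per chemo x modulator pair", {
  v <- make_viability()
  tab <- build_heatmap_table(v, chemo = c("EPI", "CIS", "PAC"),
                             modulators = c("RAP", "TOR", "WRT", "SPA",
                                            "HCQ"))
  expect_equal(sum(tab$block == "interaction"), 15)
  expect_equal(sum(tab$block == "viability"), 8)

  # identical inputs give byte-identical CSV output
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f1, row.names = FALSE)
  utils::write.csv(build_heatmap_table(v, chemo = c("EPI", "CIS", "PAC"),
                                       modulators = c("RAP", "TOR", "WRT",
                                                      "SPA", "HCQ")),
                   f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(build_heatmap_table(v[v$condition_id != "RAP", ],
                                   chemo = "EPI", modulators = "RAP"),
               "missing conditions")
})

test_that("heatmap aggregation is the median across replicates", {
  v <- data.frame(condition_id = rep(c("EPI", "RAP", "EPI+RAP"), each = 3),
                  n_total = 10,
                  n_dead = c(9, 8, 0,    0, 0, 0,    9, 8, 0))
  # live fractions: EPI [0.1, 0.2, 1] -> median 0.2; RAP 1; combo median 0.2
  tab <- build_heatmap_table(v, chemo = "EPI", modulators = "RAP")
  cell <- tab[tab$block == "interaction", ]
  expect_equal(cell$value, 0.2 * 1 - 0.2)
  expect_equal(tab$value[tab$block == "viability" & tab$chemo %in% "EPI"],
               0.2)
})

test_that("DAMP fold blocks are appended per marker and optional", {
  v <- make_viability()
  damps <- data.frame(marker = "ATP",
                      condition_id = c("CM", "CM", "EPI+RAP", "EPI+RAP"),
                      signal = c(100, 100, 240, 260))
  tab <- build_heatmap_table(v, chemo = "EPI", modulators = "RAP",
                             damps = damps)
  damp_cell <- tab[tab$block == "damp_ATP", ]
  expect_equal(damp_cell$value, 2.5)
  tab0 <- build_heatmap_table(v, chemo = "EPI", modulators = "RAP")
  expect_false(any(grepl("damp", tab0$block)))
})
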