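#!/usr/bin/env Rscript
# Fit the full 343-member hypothesis family per cell line and rank it.
#
# Each family member assigns one of 7 modes (none, or one of 3 reactions x 2
# directions) to each of EPI, CIS and PAC. Fitting is two-stage: basal rates
# and modulator strengths are estimated once on the drug-free conditions,
# then each hypothesis' drug strengths are fitted on the drug-containing
# conditions and every member is scored by the full-panel weighted SSE.
# Expect a few minutes per cell line on one core.
#
# Run analysis/01_simulate_panel.R first.

suppressPackageStartupMessages(library(pertflux))
dir.create("results/fits", recursive = TRUE, showWarnings = FALSE)

stems <- sub("_tc\\.csv$", "",
             list.files("results/timecourses", pattern = "_tc\\.csv$",
                        full.names = TRUE))
if (length(stems) == 0)
  stop("no simulated panels found; run analysis/01_simulate_panel.R first")

for (stem in stems) {
  cl <- basename(stem)
  ds <- flux_dataset(read_timecourses(paste0(stem, "_tc.csv")),
                     read_design(paste0(stem, "_design.csv")),
                     cell_line = cl)
  truth <- read.csv(paste0(stem, "_truth.csv"))
  t0 <- Sys.time()
  fits <- fit_hypotheses(ds, drugs = c("EPI", "CIS", "PAC"),
                         control = pso_control(seed = 1))
  rk <- rank_models(fits)
  write_ranking(rk, file.path("results/fits", paste0(cl, "_ranking.csv")))
  write_fit_report(rk$best,
                   file.path("results/fits", paste0(cl, "_best.json")))
  truth_id <- mode_hypothesis(stats::setNames(truth$mode, truth$drug))$id
  cat(sprintf("%-14s best: %-28s truth: %-28s rank of truth: %d (%.1f min)\n",
              cl, rk$best$hypothesis_id, truth_id,
              which(rk$table$hypothesis_id == truth_id),
              as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  for (d in names(rk$best_modes))
    cat(sprintf("    %s: %s\n", d, rk$best_modes[[d]]))
}
cat("wrote results/fits/*_{ranking.csv,best.json}\n")
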