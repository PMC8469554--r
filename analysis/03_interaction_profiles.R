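#!/usr/bin/env Rscript
# Cytotoxicity interaction and DAMP profiles from simulated readout tables.
#
# Emulates the 72 h viability assay (Hoechst/PI counts) for chemo,
# modulator and combination wells with a few built-in true interactions,
# scores every pair against Bliss independence, normalises ATP readouts
# through a standard curve, and writes the tidy heatmap table.

suppressPackageStartupMessages(library(pertflux))
dir.create("results/interactions", recursive = TRUE, showWarnings = FALSE)
set.seed(42)

chemo <- c("EPI", "CIS", "PAC")
mods <- c("RAP", "TOR", "WRT", "SPA", "HCQ")
true_live <- c(EPI = 0.55, CIS = 0.5, PAC = 0.6,
               RAP = 0.92, TOR = 0.9, WRT = 0.95, SPA = 0.97, HCQ = 0.88)
# departures from independence: RAP synergises with PAC, SPA antagonises it
shift <- matrix(0, length(chemo), length(mods),
                dimnames = list(chemo, mods))
shift["PAC", "RAP"] <- -0.25   # observed live fraction well below expected
shift["PAC", "SPA"] <- +0.30   # Spautin-1 blunts paclitaxel killing
shift["EPI", "SPA"] <- +0.25

wells <- list()
add_well <- function(cid, live) {
  n_total <- rpois(3, 800)
  n_dead <- rbinom(3, n_total, pmin(pmax(1 - live, 0), 1))
  wells[[length(wells) + 1]] <<- data.frame(condition_id = cid,
                                            n_total = n_total,
                                            n_dead = n_dead)
}
for (a in c(chemo, mods)) add_well(a, true_live[[a]])
for (d in chemo) for (m in mods)
  add_well(paste0(d, "+", m),
           pmin(pmax(true_live[[d]] * true_live[[m]] + shift[d, m], 0), 1))
viability <- do.call(rbind, wells)
write.csv(viability, "results/interactions/viability.csv", row.names = FALSE)

# ATP secretion readouts through the calibration curve, then fold change
standards <- data.frame(conc_uM = c(1, 5, 100, 250, 500, 1000))
standards$signal <- 40 + 1.9 * standards$conc_uM
atp_signal <- c(CM = 60, `EPI+HCQ` = 460, `PAC+HCQ` = 520, `CIS+HCQ` = 150)
atp <- atp_concentration(atp_signal, standards)
damps <- data.frame(marker = "ATP", condition_id = names(atp_signal),
                    signal = atp$conc_uM)
write.csv(cbind(damps, extrapolated = atp$extrapolated),
          "results/interactions/atp.csv", row.names = FALSE)

tab <- build_heatmap_table(viability, chemo = chemo, modulators = mods,
                           damps = damps)
write.csv(tab, "results/interactions/heatmap_table.csv", row.names = FALSE)

inter <- tab[tab$block == "interaction", ]
cat("classified interactions (|score| > 0.05):\n")
print(inter[inter$classification != "none",
            c("chemo", "modulator", "value", "classification")],
      row.names = FALSE)
cat(sprintf("ATP fold change EPI+HCQ vs untreated: %.1f\n",
            tab$value[tab$block == "damp_ATP" & tab$chemo == "EPI" &
                        tab$modulator == "HCQ"]))
cat("wrote results/interactions/{viability,atp,heatmap_table}.csv\n")
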