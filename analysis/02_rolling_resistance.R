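#!/usr/bin/env Rscript
# Estimate each session's rolling-resistance coefficient from its two
# coast-down trials (opposite directions, OLS slope over the trimmed coast
# phase, averaged, divided by g). Writes results/rolling_resistance.csv.
#
# Note: the estimate deliberately absorbs low-speed aerodynamic drag, exactly
# as the field method does; with the simulator's truth mu_r = 0.012 and
# CdA = 0.4 the estimates sit a little above the truth.

suppressPackageStartupMessages(library(wheelsprint))

cohort <- jsonlite::read_json("results/cohort.json", simplifyVector = TRUE)

rows <- lapply(cohort$id, function(id) {
  ses <- read_session(file.path("scratch/sessions", id, "manifest.json"))
  mu <- estimate_rolling_resistance(ses$decel_trials, ses$config$geometry_left,
                                    ses$config$system)
  data.frame(id = id, mu_r_est = as.numeric(mu),
             decel_1 = attr(mu, "decel")[1], decel_2 = attr(mu, "decel")[2])
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/rolling_resistance.csv", row.names = FALSE)

message(sprintf("mu_r estimates: mean %.4f (range %.4f-%.4f) across %d sessions",
                mean(tab$mu_r_est), min(tab$mu_r_est), max(tab$mu_r_est),
                nrow(tab)))
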