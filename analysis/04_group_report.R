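#!/usr/bin/env Rscript
# Protocol-level comparisons: WB vs WR groups, sprint 1 vs sprint 6, and ST vs
# LT, for the main performance, symmetry and trunk variables. Normality and
# homoscedasticity screens route each variable to a two-way ANOVA or
# Kruskal-Wallis; pairwise contrasts are Bonferroni-corrected; significance is
# marked at p < 0.05 (*) and p < 0.001 (**). Also fits the optional
# mixed-model sprint trend for maximal power. Writes
# results/group_report_{first_last,st_lt}_{summary,comparisons}.csv.

suppressPackageStartupMessages(library(wheelsprint))

tab <- read.csv("results/sprint_metrics.csv")
vars <- c("F_max", "V_max", "P_max", "V_mean", "V_mean_start", "sprint_time",
          "isi_start", "isi_middle", "isi_end", "isi_overall",
          "trm_start", "trm_middle", "trm_end")

# sprint 1 vs sprint 6
d16 <- tab[tab$sprint %in% c(1, 6), ]
d16$condition <- paste0("sprint", d16$sprint)
rep16 <- group_report(d16, vars, group_col = "group")
write_group_report(rep16, "results/group_report_first_last")

# shortest-time vs longest-time sprint
dst <- tab[tab$is_st | tab$is_lt, ]
dst$condition <- ifelse(dst$is_st, "ST", "LT")
dst <- dst[!(dst$is_st & dst$is_lt), ]
repst <- group_report(dst, vars, group_col = "group")
write_group_report(repst, "results/group_report_st_lt")

sig <- rep16$comparisons[rep16$comparisons$marker != "", ]
message(sprintf("sprint-1-vs-6 report: %d of %d contrasts flagged", nrow(sig),
                nrow(rep16$comparisons)))
for (i in seq_len(min(nrow(sig), 12))) {
  message(sprintf("  %-12s %-22s p = %.4g %s", sig$variable[i],
                  sig$contrast[i], sig$p[i], sig$marker[i]))
}

if (requireNamespace("lme4", quietly = TRUE)) {
  fit <- fit_sprint_trend(tab, "P_max")
  message(sprintf("mixed-model P_max trend: %.2f W per sprint",
                  lme4::fixef(fit)[["sprint"]]))
}
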