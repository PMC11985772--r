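#' Group comparison report
#'
#' Builds the descriptive mean (SD) table per variable x group x condition
#' and a thin inferential stage: per variable, normality (Shapiro-Wilk on the
#' two-way model residuals) and homoscedasticity (Levene) screens route to a
#' two-way ANOVA (group x condition) or to Kruskal-Wallis tests per factor;
#' pairwise post-hoc comparisons use Bonferroni correction. Significance is
#' marked at two tiers, p < 0.05 (`*`) and p < 0.001 (`**`).
#'
#' @param data data frame with one row per session x condition, containing
#'   `session_id`, a group column, a condition column, and the outcome
#'   variables.
#' @param variables character vector of outcome columns to analyze.
#' @param group_col,condition_col names of the grouping columns (e.g. sport
#'   group and sprint number).
#' @return An object of class `group_report`: `summary` (mean/sd/n long
#'   table) and `comparisons` (variable, contrast, test, p, marker). When any
#'   group has a single session, dispersion is reported absent and the
#'   inferential stage is skipped with a notice.
#' @export
group_report <- function(data, variables, group_col = "group",
                         condition_col = "condition") {
  stopifnot(all(c(group_col, condition_col, variables) %in% names(data)))
  G <- factor(data[[group_col]])
  C <- factor(data[[condition_col]])

  summary_tab <- do.call(rbind, lapply(variables, function(v) {
    agg <- stats::aggregate(data[[v]], list(group = G, condition = C),
                            function(z) c(mean = mean(z, na.rm = TRUE),
                                          sd = stats::sd(z, na.rm = TRUE),
                                          n = sum(is.finite(z))))
    data.frame(variable = v, group = as.character(agg$group),
               condition = as.character(agg$condition),
               mean = agg$x[, "mean"], sd = agg$x[, "sd"], n = agg$x[, "n"],
               stringsAsFactors = FALSE)
  }))
  rownames(summary_tab) <- NULL

  per_group_n <- tapply(data$session_id, G, function(z) length(unique(z)))
  if (any(per_group_n < 2L)) {
    message("group_report: a group has a single session; inferential tests skipped")
    return(structure(list(summary = summary_tab,
                          comparisons = data.frame(
                            variable = character(0), contrast = character(0),
                            test = character(0), p = numeric(0),
                            marker = character(0), stringsAsFactors = FALSE)),
                     class = "group_report"))
  }

  marker_of <- function(p) {
    ifelse(is.na(p), "", ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", "")))
  }
  two_conditions <- nlevels(C) >= 2L

  comparisons <- do.call(rbind, lapply(variables, function(v) {
    y <- data[[v]]
    ok <- is.finite(y)
    yv <- y[ok]; Gv <- droplevels(G[ok]); Cv <- droplevels(C[ok])
    form <- if (two_conditions && nlevels(Cv) >= 2L) yv ~ Gv * Cv else yv ~ Gv
    fit <- stats::aov(form)
    res <- stats::residuals(fit)
    normal_p <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA)
    lev_form <- if (two_conditions && nlevels(Cv) >= 2L) yv ~ Gv * Cv else yv ~ Gv
    homo_p <- tryCatch(car::leveneTest(lev_form)[1, "Pr(>F)"], error = function(e) NA)
    parametric <- isTRUE(normal_p > 0.05) && isTRUE(homo_p > 0.05)

    rows <- list()
    if (parametric) {
      at <- summary(fit)[[1]]
      terms <- trimws(rownames(at))
      p_of <- function(term) {
        i <- match(term, terms)
        if (is.na(i)) NA_real_ else at[i, "Pr(>F)"]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, contrast = "group", test = "two-way ANOVA",
        p = p_of("Gv"), stringsAsFactors = FALSE)
      if (two_conditions && nlevels(Cv) >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, contrast = "condition", test = "two-way ANOVA",
          p = p_of("Cv"), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, contrast = "group:condition", test = "two-way ANOVA",
          p = p_of("Gv:Cv"), stringsAsFactors = FALSE)
      }
      if (nlevels(Gv) >= 2L) {
        ph <- stats::pairwise.t.test(yv, Gv, p.adjust.method = "bonferroni")$p.value
        for (i in seq_len(nrow(ph))) for (j in seq_len(ncol(ph))) {
          if (!is.na(ph[i, j])) {
            rows[[length(rows) + 1L]] <- data.frame(
              variable = v,
              contrast = sprintf("group: %s vs %s", colnames(ph)[j], rownames(ph)[i]),
              test = "pairwise t (Bonferroni)", p = ph[i, j],
              stringsAsFactors = FALSE)
          }
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, contrast = "group", test = "Kruskal-Wallis",
        p = stats::kruskal.test(yv, Gv)$p.value, stringsAsFactors = FALSE)
      if (two_conditions && nlevels(Cv) >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, contrast = "condition", test = "Kruskal-Wallis",
          p = stats::kruskal.test(yv, Cv)$p.value, stringsAsFactors = FALSE)
      }
      if (nlevels(Gv) >= 2L) {
        ph <- suppressWarnings(
          stats::pairwise.wilcox.test(yv, Gv, p.adjust.method = "bonferroni")$p.value)
        for (i in seq_len(nrow(ph))) for (j in seq_len(ncol(ph))) {
          if (!is.na(ph[i, j])) {
            rows[[length(rows) + 1L]] <- data.frame(
              variable = v,
              contrast = sprintf("group: %s vs %s", colnames(ph)[j], rownames(ph)[i]),
              test = "pairwise Wilcoxon (Bonferroni)", p = ph[i, j],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  }))
  rownames(comparisons) <- NULL
  comparisons$marker <- marker_of(comparisons$p)
  structure(list(summary = summary_tab, comparisons = comparisons),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>\n")
  cat(sprintf("  %d summary rows, %d comparisons (%d flagged at p < 0.05)\n",
              nrow(x$summary), nrow(x$comparisons),
              sum(x$comparisons$marker != "", na.rm = TRUE)))
  invisible(x)
}

#' Write / read a group report as CSV
#'
#' Two files: `<prefix>_summary.csv` and `<prefix>_comparisons.csv`. The pair
#' round-trips exactly through [read_group_report()].
#'
#' @param report a [group_report()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly (write) / a `group_report` (read).
#' @export
write_group_report <- function(report, prefix) {
  utils::write.csv(report$summary, paste0(prefix, "_summary.csv"), row.names = FALSE)
  utils::write.csv(report$comparisons, paste0(prefix, "_comparisons.csv"),
                   row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_group_report
#' @export
read_group_report <- function(prefix) {
  comp <- utils::read.csv(paste0(prefix, "_comparisons.csv"),
                          colClasses = c(variable = "character",
                                         contrast = "character",
                                         test = "character", p = "numeric",
                                         marker = "character"))
  comp$marker[is.na(comp$marker)] <- ""
  structure(list(summary = utils::read.csv(paste0(prefix, "_summary.csv"),
                                           colClasses = c(variable = "character",
                                                          group = "character",
                                                          condition = "character")),
                 comparisons = comp),
            class = "group_report")
}

#' Mixed-model sprint trend (optional convenience)
#'
#' Fits `value ~ sprint + (1 | session_id)` with `lme4::lmer` to describe the
#' evolution of a metric across repeated sprints with a per-athlete random
#' intercept. This is routine statistics offered for convenience; no other
#' stage depends on it.
#'
#' @param data data frame with `session_id`, `sprint` and the outcome.
#' @param variable outcome column name.
#' @return The fitted `lmerMod` object.
#' @export
fit_sprint_trend <- function(data, variable) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("fit_sprint_trend: the 'lme4' package is required", call. = FALSE)
  }
  form <- stats::as.formula(paste0(variable, " ~ sprint + (1 | session_id)"))
  lme4::lmer(form, data = data)
}
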