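# Cohort descriptive summary (Table-1 style): counts and percentages for
# categorical variables, mean +/- SD and median (IQR) for continuous ones,
# with survivor vs non-survivor comparison p values.

#' Descriptive cohort summary by outcome group
#'
#' One row per (variable, statistic): categorical variables yield `n` and
#' `percent` per level (percentages against the analysed N of each column),
#' continuous variables yield `mean`, `sd`, `median`, `q1`, `q3` (quartiles
#' by linear interpolation, `quantile type 7`). Group comparison p values
#' use one-way ANOVA for continuous variables and the chi-square test for
#' categorical ones; `p_label` marks `ns` at p >= 0.05.
#'
#' @param data Data.frame with one row per subject.
#' @param group Name of the grouping column (default `"outcome"`).
#' @param variables Columns to summarise; defaults to all except the group
#'   and `*_id` columns.
#' @return A `descriptive_table` data.frame with columns `variable`,
#'   `level`, `statistic`, `overall`, one column per group, `p`, `p_label`.
#' @export
descriptive_table <- function(data, group = "outcome", variables = NULL) {
  if (!nrow(data)) {
    stop_sepsimet("sepsimet_invalid_argument", "empty cohort")
  }
  g <- as.factor(data[[group]])
  if (is.null(variables)) {
    variables <- setdiff(names(data),
                         c(group, grep("_id$|^conc\\.", names(data),
                                       value = TRUE)))
  }
  groups <- levels(g)
  rows <- list()
  add_row <- function(variable, level, statistic, overall, per_group, p) {
    row <- data.frame(variable = variable, level = level,
                      statistic = statistic, overall = overall,
                      stringsAsFactors = FALSE)
    for (gn in groups) row[[gn]] <- per_group[[gn]]
    row$p <- p
    rows[[length(rows) + 1L]] <<- row
  }
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- tryCatch(stats::oneway.test(x ~ g, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
      stats_fns <- list(
        mean = mean, sd = stats::sd, median = stats::median,
        q1 = function(z) unname(stats::quantile(z, 0.25)),
        q3 = function(z) unname(stats::quantile(z, 0.75)))
      for (st in names(stats_fns)) {
        f <- stats_fns[[st]]
        add_row(v, NA_character_, st, f(x),
                lapply(stats::setNames(groups, groups),
                       function(gn) f(x[g == gn])), p)
      }
    } else {
      x <- as.factor(x)
      tab <- table(x, g)
      p <- if (nlevels(x) > 1) {
        tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                 error = function(e) NA_real_)
      } else NA_real_
      for (lev in levels(x)) {
        n_lev <- sum(x == lev)
        add_row(v, lev, "n", n_lev,
                lapply(stats::setNames(groups, groups),
                       function(gn) sum(x == lev & g == gn)), p)
        add_row(v, lev, "percent", round(100 * n_lev / length(x), 1),
                lapply(stats::setNames(groups, groups),
                       function(gn) round(100 * sum(x == lev & g == gn) /
                                            sum(g == gn), 1)), p)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_label <- ifelse(is.na(out$p), "",
                        ifelse(out$p >= 0.05, "ns",
                               ifelse(out$p < 0.001, "<0.001",
                                      ifelse(out$p < 0.01, "<0.01", "<0.05"))))
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' Group share of the cohort as a printed percentage
#'
#' Convenience for headline rates such as 30-day mortality: `k` of `n` as a
#' percentage rounded to one decimal, with a Wilson confidence interval.
#'
#' @param k Count in the category.
#' @param n Analysed total.
#' @param conf_level CI level.
#' @return List: `percent`, `ci` (percent scale).
#' @export
cohort_rate <- function(k, n, conf_level = 0.95) {
  ci <- wilson_ci(k, n, conf_level)
  list(percent = round(100 * k / n, 1),
       ci = round(100 * ci, 1))
}
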