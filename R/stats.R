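# Group comparison: one-way ANOVA with Tukey HSD post hoc, plus
# descriptive summaries (mean, SD, SEM, deaths) per arm.

groups_to_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "total") %in% names(groups)))
    return(data.frame(group = as.character(groups$group),
                      total = as.numeric(groups$total),
                      stringsAsFactors = FALSE))
  }
  data.frame(group = rep(names(groups), lengths(groups)),
             total = as.numeric(unlist(groups)), stringsAsFactors = FALSE)
}

check_anova_input <- function(df) {
  k <- length(unique(df$group))
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  n <- table(df$group)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  ssw <- sum(tapply(df$total, df$group,
                    function(x) sum((x - mean(x))^2)))
  if (ssw <= 0)
    stop("degenerate input: zero pooled within-group variance", call. = FALSE)
  if (any(tapply(df$total, df$group, stats::var) == 0))
    warning("a group is all-tied (e.g. all deaths at the maximum score); ",
            "ANOVA assumptions are strained", call. = FALSE)
  invisible(df)
}

#' One-way ANOVA on cohort totals
#'
#' F = (between-group SS / (k - 1)) / (within-group SS / (N - k)); p from
#' the upper tail of the F distribution. Accepts either a named list of
#' per-group score vectors or a scores data frame with `group` and `total`
#' columns.
#'
#' @param groups Named list label -> numeric totals, or a data frame.
#' @return List with `F`, `df_between`, `df_within`, `p`, `group_means`,
#'   `grand_mean`.
#' @export
anova_oneway <- function(groups) {
  df <- check_anova_input(groups_to_df(groups))
  fit <- stats::aov(total ~ group, data = df)
  tab <- summary(fit)[[1]]
  gm <- tapply(df$total, df$group, mean)
  list(F = tab["group", "F value"],
       df_between = tab["group", "Df"],
       df_within = tab["Residuals", "Df"],
       p = tab["group", "Pr(>F)"],
       group_means = stats::setNames(as.numeric(gm), names(gm)),
       grand_mean = mean(df$total))
}

#' Tukey HSD post hoc table
#'
#' All pairwise comparisons following the one-way ANOVA, using the
#' Tukey-Kramer studentized-range statistic for (possibly) unequal group
#' sizes: q = |m_i - m_j| / sqrt(MSW/2 * (1/n_i + 1/n_j)), with adjusted p
#' from the studentized-range distribution on (k, N - k).
#'
#' @inheritParams anova_oneway
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_diff` (a - b), `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  df <- check_anova_input(groups_to_df(groups))
  fit <- stats::aov(total ~ group, data = df)
  thsd <- stats::TukeyHSD(fit)$group
  msw <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  n <- table(df$group)
  pairs <- do.call(rbind, strsplit(rownames(thsd), "-", fixed = TRUE))
  q <- abs(thsd[, "diff"]) /
    sqrt(msw / 2 * (1 / n[pairs[, 1]] + 1 / n[pairs[, 2]]))
  out <- data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
                    mean_diff = unname(thsd[, "diff"]), q = as.numeric(q),
                    p_adj = unname(thsd[, "p adj"]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group descriptive summaries
#'
#' Reports both SD and SEM (figures in this field alternate between the
#' two), plus the death count per arm.
#'
#' @param cohort A `cohort_scores`, or its `scores` data frame.
#' @return Data frame with one row per group: `group`, `n`, `mean`, `sd`
#'   (sample, n - 1), `sem`, `min`, `max`, `deaths`.
#' @export
summarize_cohort <- function(cohort) {
  sc <- if (inherits(cohort, "cohort_scores")) cohort$scores else cohort
  out <- do.call(rbind, lapply(split(sc, sc$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean = mean(g$total),
               sd = stats::sd(g$total),
               sem = stats::sd(g$total) / sqrt(nrow(g)),
               min = min(g$total), max = max(g$total),
               deaths = sum(g$died), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
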