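# Weight-perturbation rank-stability analysis: are arm toxicity rankings
# preserved when the rubric's relative weightings change?

#' Perturbation settings
#'
#' @param factor_range Multiplicative bound f > 1; factors are drawn
#'   log-uniformly from \[1/f, f\] so up- and down-weighting are symmetric.
#' @param n_perturbations Number of perturbed rubrics.
#' @param seed Integer seed; together with a draw index it fully determines
#'   each perturbed rubric.
#' @param scope `"per_category"` (default): one factor per scoring category,
#'   with the death score tied to the seizure factor — the factor-level
#'   variation of "death, seizures, and the various other behavioral
#'   observations". `"per_cell"`: every nonzero table cell jittered
#'   independently, then re-sorted within its row to preserve monotonicity.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(factor_range = 2, n_perturbations = 1000,
                              seed = 1L, scope = c("per_category", "per_cell")) {
  scope <- match.arg(scope)
  if (!is.numeric(factor_range) || factor_range < 1)
    stop("factor_range must be >= 1", call. = FALSE)
  if (n_perturbations < 1) stop("n_perturbations must be >= 1", call. = FALSE)
  structure(list(factor_range = factor_range,
                 n_perturbations = as.integer(n_perturbations),
                 seed = as.integer(seed), scope = scope),
            class = "perturbation_spec")
}

# Deterministic substream seed from (seed, draw_index); doubles are exact
# here, keep the result inside 32-bit range.
substream_seed <- function(seed, index, salt = 0) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 +
                salt) %% 2147483629)
}

#' Draw one perturbed rubric
#'
#' Deterministic in `(spec$seed, draw_index)`. Per-category scope multiplies
#' each of the six category rows by an independent log-uniform factor from
#' \[1/f, f\], with the death score scaled by the seizure factor; per-cell
#' scope jitters every nonzero cell and re-sorts within rows. In either
#' scope, if the perturbed death score falls below a perturbed category
#' maximum it is raised to that maximum so the result remains a valid
#' rubric. The factors used are attached as attribute `"factors"`.
#'
#' @param r A valid `evadint_rubric`.
#' @param spec A `perturbation_spec`.
#' @param draw_index Which perturbation (1-based).
#' @return A valid perturbed `evadint_rubric`.
#' @export
perturb_rubric <- function(r, spec, draw_index = 1L) {
  stop_if_invalid_rubric(r)
  f <- spec$factor_range
  lf <- log(f)
  set.seed(substream_seed(spec$seed, draw_index))
  cats <- c(EVENT_CATEGORIES, LATENCY_CATEGORIES)
  if (spec$scope == "per_category") {
    fac <- stats::setNames(exp(stats::runif(length(cats), -lf, lf)), cats)
    for (cat in EVENT_CATEGORIES) r$events[[cat]] <- r$events[[cat]] * fac[[cat]]
    for (cat in LATENCY_CATEGORIES) r$latency[[cat]] <- r$latency[[cat]] * fac[[cat]]
    r$death_score <- r$death_score * fac[["seizure"]]
  } else {
    fac <- list()
    for (cat in EVENT_CATEGORIES) {
      w <- r$events[[cat]] * exp(stats::runif(length(r$events[[cat]]), -lf, lf))
      r$events[[cat]][] <- sort(w)  # zero at 'none' survives: 0 * anything = 0
      fac[[cat]] <- w
    }
    for (cat in LATENCY_CATEGORIES) {
      w <- r$latency[[cat]] * exp(stats::runif(length(r$latency[[cat]]), -lf, lf))
      r$latency[[cat]][] <- sort(w)
      fac[[cat]] <- w
    }
    r$death_score <- r$death_score * exp(stats::runif(1, -lf, lf))
  }
  cap <- max(vapply(r$events, max, numeric(1)),
             vapply(r$latency, max, numeric(1)))
  if (r$death_score < cap) r$death_score <- cap
  attr(r, "factors") <- fac
  stop_if_invalid_rubric(r)
  r
}

#' Rank concordance between two group-score maps
#'
#' Kendall tau-b (tie-corrected) between two vectors of group summaries
#' sharing the same group keys.
#'
#' @param means_a,means_b Named numeric vectors, same names (any order).
#' @return Tau-b in \[-1, 1\].
#' @export
rank_concordance <- function(means_a, means_b) {
  if (length(means_a) < 2 || !setequal(names(means_a), names(means_b)))
    stop("need >= 2 groups with identical keys", call. = FALSE)
  b <- means_b[names(means_a)]
  tau <- suppressWarnings(
    stats::cor(as.numeric(means_a), as.numeric(b), method = "kendall"))
  if (is.na(tau))
    stop("rank concordance undefined: a vector is all-tied", call. = FALSE)
  tau
}

#' Weight-robustness analysis
#'
#' Scores the cohort under the baseline rubric, then under `n` perturbed
#' rubrics, and measures how often the arm ranking by mean total survives
#' re-weighting. Animal-level scoring features (event severities, recovery
#' checkpoints, survival) are rubric-independent and extracted once.
#'
#' @param obs List of `mouse_observation` covering >= 2 groups.
#' @param r Baseline `evadint_rubric`.
#' @param spec A `perturbation_spec`.
#' @return A `robustness_report`: list with `baseline_means` (named, sorted
#'   decreasing), `baseline_ranking` (group labels, most to least toxic),
#'   `tau` (per-perturbation Kendall tau-b vs baseline), `fraction_perfect`,
#'   `mean_tau`, `min_tau`, and the `spec`.
#' @export
robustness_analysis <- function(obs, r = default_rubric(), spec = perturbation_spec()) {
  feats <- lapply(obs, extract_score_features)
  groups <- vapply(feats, function(f) f$group, character(1))
  if (length(unique(groups)) < 2)
    stop("robustness analysis needs >= 2 groups", call. = FALSE)
  group_means <- function(rub) {
    totals <- vapply(feats, function(f) score_features(f, rub)$total,
                     numeric(1))
    tapply(totals, groups, mean)
  }
  base <- group_means(r)
  tau <- vapply(seq_len(spec$n_perturbations), function(i) {
    rank_concordance(base, group_means(perturb_rubric(r, spec, i)))
  }, numeric(1))
  structure(list(
    baseline_means = sort(base, decreasing = TRUE),
    baseline_ranking = names(sort(base, decreasing = TRUE)),
    tau = tau,
    # floating-point pair counting can land at 1 - eps; snap within 1e-9
    fraction_perfect = mean(tau >= 1 - 1e-9),
    mean_tau = mean(tau),
    min_tau = min(tau),
    spec = spec
  ), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Weight-robustness report\n")
  cat("  baseline ranking:", paste(x$baseline_ranking, collapse = " > "), "\n")
  cat(sprintf("  %d perturbations, factor %g, scope %s, seed %d\n",
              x$spec$n_perturbations, x$spec$factor_range, x$spec$scope,
              x$spec$seed))
  cat(sprintf("  fraction with perfect concordance: %.3f\n", x$fraction_perfect))
  cat(sprintf("  tau: mean %.3f, min %.3f\n", x$mean_tau, x$min_tau))
  invisible(x)
}
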