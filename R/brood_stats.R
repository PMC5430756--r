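#' Pearson goodness-of-fit test of a brood sex ratio
#'
#' Tests observed male/female counts against an expected male proportion
#' with a 1-df Pearson chi-square statistic, no continuity correction
#' (the convention used throughout the crossing analyses; a Yates-corrected
#' variant is available via `correct`).
#'
#' @param n_male,n_female non-negative integer counts, total > 0.
#' @param expected_male_prop expected male proportion, strictly inside
#'   (0, 1). A degenerate expectation of exactly 0 or 1 is rejected:
#'   use [exact_zero_male_test()] for the all-female XY prediction.
#' @param correct logical; apply Yates continuity correction (default
#'   `FALSE`).
#' @return list with `statistic` and `p.value`.
#' @examples
#' chisq_gof(10, 20, 0.5)   # statistic 10/3, p ~ 0.068
#' @export
chisq_gof <- function(n_male, n_female, expected_male_prop, correct = FALSE) {
  check_counts(n_male, n_female)
  if (!is.numeric(expected_male_prop) || length(expected_male_prop) != 1L ||
      is.na(expected_male_prop) ||
      expected_male_prop <= 0 || expected_male_prop >= 1)
    stop("degenerate expectation: expected_male_prop must lie strictly in ",
         "(0, 1); use exact_zero_male_test() for an all-female prediction",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(
    c(n_male, n_female),
    p = c(expected_male_prop, 1 - expected_male_prop),
    correct = correct))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Exact test of the all-female XY prediction
#'
#' Under male heterogamety a neomale (XX) x sister (XX) cross predicts 100%
#' XX females, an expectation at which the chi-square test is undefined.
#' This exact binomial test gives the upper-tail probability of observing
#' at least `n_male` males when each offspring is male with probability
#' `male_leak_rate` (a nuisance rate for incomplete sex reversal or sexing
#' error; default 0). With zero leak, a single male falsifies the strict
#' XY prediction (p = 0) and an all-female brood is fully consistent
#' (p = 1).
#'
#' @inheritParams chisq_gof
#' @param male_leak_rate probability in `[0, 1)` that an offspring is male
#'   under the XY null.
#' @return upper-tail p-value.
#' @examples
#' exact_zero_male_test(0, 40)            # 1
#' exact_zero_male_test(2, 38, 0.02)      # ~0.19
#' @export
exact_zero_male_test <- function(n_male, n_female, male_leak_rate = 0) {
  check_counts(n_male, n_female)
  if (!is.numeric(male_leak_rate) || length(male_leak_rate) != 1L ||
      is.na(male_leak_rate) || male_leak_rate < 0 || male_leak_rate >= 1)
    stop("male_leak_rate must lie in [0, 1)", call. = FALSE)
  n <- n_male + n_female
  if (male_leak_rate == 0) return(if (n_male == 0) 1 else 0)
  # P(X >= n_male), X ~ Binomial(n, leak)
  stats::pbinom(n_male - 1, n, male_leak_rate, lower.tail = FALSE)
}

#' Heterogeneity of sex ratios among broods of one species
#'
#' Pearson chi-square test of independence on the brood x sex contingency
#' table, df = (#broods - 1). A non-significant result licenses pooling
#' sex counts across broods before classifying the species.
#'
#' @param broods data frame with columns `n_male`, `n_female`, one row per
#'   brood (at least two broods, each with a positive total).
#' @return list with `statistic`, `p.value`, `df`.
#' @export
heterogeneity_test <- function(broods) {
  stopifnot(is.data.frame(broods),
            all(c("n_male", "n_female") %in% names(broods)))
  if (nrow(broods) < 2L)
    stop("heterogeneity requires at least two broods", call. = FALSE)
  m <- as.matrix(broods[, c("n_male", "n_female")])
  if (any(rowSums(m) <= 0))
    stop("every brood must have a positive total", call. = FALSE)
  if (any(colSums(m) == 0))
    stop("degenerate table: one sex has zero total across all broods",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter))
}

check_counts <- function(n_male, n_female) {
  if (!is.numeric(n_male) || !is.numeric(n_female) ||
      length(n_male) != 1L || length(n_female) != 1L ||
      is.na(n_male) || is.na(n_female) ||
      n_male < 0 || n_female < 0 || n_male + n_female < 1)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  invisible(TRUE)
}

#' Monte-Carlo power of the sex-ratio chi-square test
#'
#' Estimates the probability of rejecting a null male proportion at level
#' `alpha` when broods of `brood_total` offspring are truly binomial with
#' `true_male_prop`. Used to quantify how large a pooled progeny must be to
#' separate the 1/4 (WW viable) from the 1/3 (WW inviable) prediction --
#' e.g. the 30 offspring obtained for Porcellio scaber give power well
#' under 30% against the 1/3 null.
#'
#' @param brood_total pooled offspring count per replicate.
#' @param true_male_prop,null_male_prop proportions in (0, 1).
#' @param alpha significance level.
#' @param n_sim number of Monte-Carlo replicates.
#' @param seed integer seed (local to the call).
#' @return estimated power (proportion of rejections).
#' @export
viability_power <- function(brood_total, true_male_prop, null_male_prop,
                            alpha = 0.05, n_sim = 10000, seed = 1) {
  stopifnot(n_sim >= 1, brood_total >= 1,
            true_male_prop > 0, true_male_prop < 1,
            null_male_prop > 0, null_male_prop < 1)
  males <- local_seed(seed, stats::rbinom(n_sim, brood_total, true_male_prop))
  e_m <- brood_total * null_male_prop
  e_f <- brood_total - e_m
  stat <- (males - e_m)^2 / e_m + ((brood_total - males) - e_f)^2 / e_f
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  mean(p < alpha)
}

# run expr under a temporary RNG state, restoring the caller's state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
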