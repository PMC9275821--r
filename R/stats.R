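# Two-sample comparison statistics used throughout the mutant analyses.

#' Group summary
#'
#' @param mean sample mean.
#' @param sd sample standard deviation (n - 1 denominator).
#' @param n sample size (>= 1).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(n >= 1, sd >= 0)
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "group_summary")
}

#' @rdname group_summary
#' @param x numeric vector to summarize.
#' @export
summarize_group <- function(x) {
  group_summary(mean(x), stats::sd(x), length(x))
}

#' Two-sample z-score
#'
#' `Z = (mean_a - mean_b) / sqrt(sd_a^2 / n_a + sd_b^2 / n_b)`
#' (unequal-variance form). Antisymmetric under swapping the groups. With
#' zero pooled variance and unequal means the result is signed infinity.
#'
#' @param a,b [group_summary()] objects (e.g. mutant and control).
#' @return the z-score.
#' @export
z_score <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"),
            a$n >= 2, b$n >= 2)
  denom <- sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
  if (denom == 0) {
    if (a$mean == b$mean) return(0)
    return(sign(a$mean - b$mean) * Inf)
  }
  (a$mean - b$mean) / denom
}

#' One-sided p-value from a z-score
#'
#' `p = erfc(-Z / sqrt(2)) / 2`, the lower-tail normal probability:
#' strongly negative Z (mutant far below control) gives a small p.
#'
#' @param z z-score (finite).
#' @return p in (0, 1), monotone in `z`.
#' @export
one_sided_p <- function(z) {
  stopifnot(is.finite(z))
  stats::pnorm(z)
}

#' Standard error of a proportion
#'
#' `SE = sqrt(p_hat (1 - p_hat) / N)` for the observed frequency `p_hat`
#' of an all-or-nothing outcome over `N` trials.
#'
#' @param p_hat observed frequency in `[0, 1]`.
#' @param N number of trials (>= 1).
#' @return the standard error, in `[0, 0.5 / sqrt(N)]`.
#' @export
proportion_se <- function(p_hat, N) {
  stopifnot(p_hat >= 0, p_hat <= 1, N >= 1)
  sqrt(p_hat * (1 - p_hat) / N)
}

#' Compare fold-count distributions between two conditions
#'
#' Summarizes the number of folds formed per embryo in each condition and
#' compares the means with the two-sample z-score and its one-sided p.
#' Also reports the three-fold success frequencies with their standard
#' errors.
#'
#' @param outcomes_a,outcomes_b tibbles with columns `folds` (0-3) and
#'   optionally `success`.
#' @return tibble with one row: means, SDs, z, p, success frequencies, SEs.
#' @export
compare_fold_counts <- function(outcomes_a, outcomes_b) {
  if (nrow(outcomes_a) < 2 || nrow(outcomes_b) < 2) {
    stop("both groups need at least two embryos")
  }
  ga <- summarize_group(outcomes_a$folds)
  gb <- summarize_group(outcomes_b$folds)
  z <- z_score(ga, gb)
  pa <- mean(outcomes_a$folds == 3)
  pb <- mean(outcomes_b$folds == 3)
  tibble::tibble(
    mean_folds_a = ga$mean, mean_folds_b = gb$mean,
    sd_a = ga$sd, sd_b = gb$sd,
    n_a = ga$n, n_b = gb$n,
    z = z, p = one_sided_p(z),
    p_hat_a = pa, se_a = proportion_se(pa, ga$n),
    p_hat_b = pb, se_b = proportion_se(pb, gb$n)
  )
}
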