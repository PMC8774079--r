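# Closed-form detoxification and cross-compatibility probabilities.
#
# A pollen grain carries n SLF types; each independently detoxifies a given
# S-RNase with per-pair probability PR, so the grain detoxifies that RNase
# with probability Pn = 1 - (1 - PR)^n. A heterozygous style carries two
# S-RNases, both of which must be detoxified, giving a style-acceptance
# rate of Pn^2.

#' Detoxification model parameters
#'
#' @param p_r Per-pair detoxification/recognition probability PR in \[0, 1\].
#' @param n Number of SLF types carried by the pollen (non-negative integer).
#' @return Object of class `detox_params`.
#' @examples
#' detox_params(0.85, 1)
#' @export
detox_params <- function(p_r, n = 1L) {
  if (!is.numeric(p_r) || p_r < 0 || p_r > 1) {
    stop_input("p_r must be a probability in [0, 1]")
  }
  if (n < 0 || n != round(n)) stop_input("n must be a non-negative integer")
  structure(list(p_r = as.numeric(p_r), n = as.integer(n)),
            class = "detox_params")
}

#' @export
print.detox_params <- function(x, ...) {
  cat("<detox_params> PR =", x$p_r, ", n =", x$n,
      "SLF type(s); Pn =", format(detox_prob_n(x), digits = 6), "\n")
  invisible(x)
}

as_detox_params <- function(params, n = NULL) {
  if (inherits(params, "detox_params")) {
    if (!is.null(n)) params$n <- as.integer(n)
    params
  } else {
    detox_params(params, n %||% 1L)
  }
}

#' Probability that pollen with n SLF types detoxifies one S-RNase
#'
#' `Pn = 1 - (1 - PR)^n`: each of the n SLF types independently recognizes
#' the RNase with probability PR.
#'
#' @param params [detox_params()] (or a bare PR with `n` supplied).
#' @param n Optional override of the number of SLF types.
#' @return Probability.
#' @examples
#' detox_prob_n(detox_params(0.85, 1))  # 0.85
#' detox_prob_n(detox_params(0.85, 2))  # 0.9775
#' @export
detox_prob_n <- function(params, n = NULL) {
  params <- as_detox_params(params, n)
  1 - (1 - params$p_r)^params$n
}

#' Fraction of styles accepting the pollen
#'
#' A style carrying `rnases_per_style` S-RNases (2 for a heterozygote)
#' accepts the pollen only if every one is detoxified:
#' `Pn^rnases_per_style`, unrounded.
#'
#' @inheritParams detox_prob_n
#' @param rnases_per_style Number of S-RNases per style (default 2).
#' @return Probability.
#' @examples
#' style_acceptance(detox_params(0.85, 1))  # 0.7225, i.e. 72%
#' style_acceptance(detox_params(0.5, 1))   # 0.25
#' @export
style_acceptance <- function(params, rnases_per_style = 2L, n = NULL) {
  if (rnases_per_style < 1) stop_input("rnases_per_style must be >= 1")
  detox_prob_n(params, n)^rnases_per_style
}

#' Report a probability as an integer percentage
#'
#' Rounds half-up to whole percent (the presentation convention for
#' acceptance rates such as 72%, 96%, 25%).
#'
#' @param p Probability.
#' @return Integer percent.
#' @examples
#' percent(style_acceptance(detox_params(0.85, 1)))  # 72
#' @export
percent <- function(p) {
  floor(100 * p + 0.5)
}

#' Estimate PR from aggregated success/trial counts
#'
#' Point estimate successes/trials with an exact (Clopper-Pearson) interval;
#' trials are (SLF, S-RNase) pairs and successes the detoxified pairs.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`.
#' @param ci_level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `successes`, `trials`,
#'   `ci_level`.
#' @examples
#' estimate_p_r(22, 26)  # 0.846, CI [0.651, 0.956]
#' @export
estimate_p_r <- function(successes, trials, ci_level = 0.95) {
  if (trials <= 0) stop_input("trials must be positive")
  if (successes < 0 || successes > trials) {
    stop_input("need 0 <= successes <= trials")
  }
  bt <- stats::binom.test(successes, trials, conf.level = ci_level)
  list(estimate = successes / trials,
       lower = bt$conf.int[1], upper = bt$conf.int[2],
       successes = successes, trials = trials, ci_level = ci_level)
}

#' Aggregate per-transgene specificity calls into success/trial counts
#'
#' Each specificity ([detox_spec()]) is scored against the full allele
#' universe: trials = number of specs times universe size, successes =
#' total detoxified (spec, allele) pairs.
#'
#' @param specs List of [detox_spec()] objects.
#' @param allele_universe Character vector of S-RNase alleles each spec was
#'   tested against.
#' @return List with `successes` and `trials`.
#' @export
aggregate_specificity_calls <- function(specs, allele_universe) {
  if (!length(specs) || !length(allele_universe)) {
    stop_input("specs and allele_universe must be non-empty")
  }
  hits <- vapply(specs, function(sp) {
    bad <- setdiff(sp$targets, allele_universe)
    if (length(bad)) {
      stop_input("spec ", sp$source_id, " targets outside the universe: ",
                 paste(bad, collapse = ", "))
    }
    length(intersect(sp$targets, allele_universe))
  }, integer(1))
  list(successes = sum(hits),
       trials = length(specs) * length(allele_universe))
}

#' Chi-squared goodness-of-fit for an observed detoxification rate
#'
#' Standard 1-df chi-squared test of (successes, failures) against
#' (trials * p, trials * (1 - p)), no continuity correction, with a
#' companion two-sided exact binomial p-value (expected counts this small
#' make the chi-squared approximation borderline).
#'
#' @param successes,trials Counts.
#' @param expected_p Null success probability in (0, 1).
#' @return List with `statistic`, `df`, `p_value`, `binom_p_value`.
#' @examples
#' goodness_of_fit(22, 26, 5 / 26)  # chi-squared ~= 71.56
#' @export
goodness_of_fit <- function(successes, trials, expected_p) {
  if (trials <= 0) stop_input("trials must be positive")
  if (expected_p <= 0 || expected_p >= 1) {
    stop_input("expected_p must be in (0, 1)")
  }
  obs <- c(successes, trials - successes)
  chs <- suppressWarnings(
    stats::chisq.test(obs, p = c(expected_p, 1 - expected_p),
                      correct = FALSE))
  list(statistic = unname(chs$statistic),
       df = unname(chs$parameter),
       p_value = chs$p.value,
       binom_p_value = stats::binom.test(successes, trials,
                                         p = expected_p)$p.value)
}

#' Monte-Carlo style-acceptance rate
#'
#' Simulates, for `n_pairs` pollen-on-style trials, independent
#' Bernoulli(PR) detoxification events for each of the pollen's n SLF types
#' against each of the style's S-RNases; a style accepts when every RNase
#' is hit by at least one SLF. Validates the closed form
#' [style_acceptance()].
#'
#' @inheritParams style_acceptance
#' @param n_pairs Number of simulated pollinations.
#' @param seed RNG seed.
#' @return Empirical acceptance fraction.
#' @export
simulate_acceptance <- function(params, n_pairs, seed,
                                rnases_per_style = 2L, n = NULL) {
  params <- as_detox_params(params, n)
  if (n_pairs < 1) stop_input("n_pairs must be >= 1")
  with_seed(seed, {
    # hits per (trial, RNase): number of the n SLFs that recognize it
    hits <- matrix(stats::rbinom(n_pairs * rnases_per_style,
                                 size = params$n, prob = params$p_r),
                   nrow = n_pairs)
    mean(rowSums(hits > 0) == rnases_per_style)
  })
}
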