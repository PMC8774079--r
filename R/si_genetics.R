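# Pollination genetics under collaborative non-self recognition.
#
# Type-1 gametophytic SI: a haploid pollen grain growing through a
# heterozygous style must detoxify BOTH style S-RNases to fertilize. The
# pollen haplotype's endogenous SLF repertoire detoxifies nonself S-RNases
# but never its own; a transgene adds an extra repertoire, and if that
# repertoire covers the self S-RNase the pollen becomes compatible on its
# own style (competitive interaction -> breakdown of SI).

resolve_universe <- function(parent_alleles, style_alleles = NULL,
                             universe = NULL) {
  u <- unique(c(parent_alleles, style_alleles, universe))
  u[!is.na(u)]
}

#' Is a pollen grain compatible on a given style?
#'
#' A pollen grain is compatible iff every style S-RNase is detoxified by the
#' union of (a) the pollen haplotype's endogenous SLF repertoire — by default
#' all nonself alleles, never its own — and (b) the transgene's targets when
#' the grain carries the transgene. The self S-RNase (same allele as the
#' pollen) is therefore detoxified only when it is among the transgene
#' targets.
#'
#' @param pollen_allele S-allele name of the haploid pollen grain.
#' @param style_alleles Character vector (usually length 2) of style
#'   S-RNase alleles.
#' @param transgene [detox_spec()] of the transgene, or `NULL` for
#'   non-transgenic pollen.
#' @param carries_transgene Does this grain carry the transgene? Default
#'   `TRUE` whenever `transgene` is non-NULL.
#' @param endogenous_specs Optional named list of [detox_spec()] overriding
#'   the default complete-nonself endogenous repertoire, keyed by haplotype
#'   (allele) name.
#' @param universe Allele universe; defaults to the alleles mentioned.
#' @return Logical flag.
#' @examples
#' pollen_compatible("S3", c("S3", "S3L"))                       # FALSE: self
#' pollen_compatible("S3L", c("S3", "S3L"),
#'                   transgene = detox_spec("tg", "S3L"))        # TRUE
#' @export
pollen_compatible <- function(pollen_allele, style_alleles, transgene = NULL,
                              carries_transgene = !is.null(transgene),
                              endogenous_specs = NULL, universe = NULL) {
  if (is.null(universe)) {
    universe <- unique(c(pollen_allele, style_alleles))
  }
  if (!pollen_allele %in% universe ||
      length(setdiff(style_alleles, universe))) {
    stop_input("unknown allele name among pollen/style alleles")
  }
  endo <- if (!is.null(endogenous_specs) &&
              pollen_allele %in% names(endogenous_specs)) {
    sp <- endogenous_specs[[pollen_allele]]
    if (pollen_allele %in% sp$targets) {
      stop_input("endogenous repertoire of ", pollen_allele,
                 " must not detoxify its own allele")
    }
    sp$targets
  } else {
    setdiff(universe, pollen_allele)  # complete collaborative network
  }
  tg <- if (carries_transgene && !is.null(transgene)) transgene$targets
        else character()
  all(style_alleles %in% union(endo, tg))
}

pollen_classes <- function(parent_alleles, transgene_zygosity) {
  f <- switch(transgene_zygosity, hemizygous = 0.5, homozygous = 1,
              stop_input("transgene_zygosity must be hemizygous or homozygous"))
  out <- expand.grid(s_allele = parent_alleles,
                     carries_transgene = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  out$probability <- 0.5 * ifelse(out$carries_transgene, f, 1 - f)
  out[out$probability > 0, , drop = FALSE]
}

#' Does a transgene break down SI in a self-cross?
#'
#' TRUE iff at least one transgenic pollen class is compatible on the
#' parent's own style. Competitive interaction: SI breaks down when the
#' transgene detoxifies at least one of the parent's S-RNases that would
#' otherwise reject the matching self pollen.
#'
#' @param parent_alleles Character vector of length 2 (unordered allele
#'   pair; identical entries for a homozygote).
#' @inheritParams pollen_compatible
#' @return Logical flag.
#' @examples
#' predict_breakdown(c("S3", "S3L"), detox_spec("ctrl", character()))  # FALSE
#' predict_breakdown(c("S3", "S3L"), detox_spec("tg", "S3L"))          # TRUE
#' @export
predict_breakdown <- function(parent_alleles, transgene,
                              endogenous_specs = NULL, universe = NULL) {
  stopifnot(length(parent_alleles) == 2)
  any(vapply(unique(parent_alleles), function(p) {
    pollen_compatible(p, parent_alleles, transgene,
                      carries_transgene = TRUE,
                      endogenous_specs = endogenous_specs,
                      universe = universe)
  }, logical(1)))
}

#' Predicted self-progeny genotype distribution under competitive interaction
#'
#' Enumerates the pollen classes of a transgenic self-cross (each parental
#' S-allele at 1/2; the transgene segregating as a single unlinked locus:
#' half of each class for a hemizygote, all for a homozygote), keeps the
#' compatible classes, renormalizes, and combines with the maternal alleles
#' (1/2 each) into unordered diploid genotype probabilities.
#'
#' @inheritParams predict_breakdown
#' @param transgene_zygosity `"hemizygous"` (default; a T0 transformant) or
#'   `"homozygous"`.
#' @return Named numeric vector of probabilities over the three possible
#'   genotype labels (see [genotype_label()]); sums to 1.
#' @examples
#' predict_progeny(c("S3", "S3L"), detox_spec("tg", "S3L"))
#' # S3/S3 = 0, S3/S3L = 0.5, S3L/S3L = 0.5
#' @export
predict_progeny <- function(parent_alleles, transgene,
                            transgene_zygosity = c("hemizygous", "homozygous"),
                            endogenous_specs = NULL, universe = NULL) {
  stopifnot(length(parent_alleles) == 2)
  transgene_zygosity <- match.arg(transgene_zygosity)
  universe <- resolve_universe(parent_alleles, universe = universe)

  pc <- pollen_classes(parent_alleles, transgene_zygosity)
  ok <- vapply(seq_len(nrow(pc)), function(i) {
    pollen_compatible(pc$s_allele[i], parent_alleles, transgene,
                      carries_transgene = pc$carries_transgene[i],
                      endogenous_specs = endogenous_specs,
                      universe = universe)
  }, logical(1))
  pc <- pc[ok, , drop = FALSE]
  if (nrow(pc) == 0L) {
    stop_input("fully incompatible cross: no compatible pollen class")
  }
  pc$probability <- pc$probability / sum(pc$probability)

  a <- sort(unique(parent_alleles))
  labels <- unique(as.vector(outer(parent_alleles, parent_alleles,
                                   genotype_label)))
  out <- stats::setNames(numeric(length(labels)), sort(labels))
  for (m in parent_alleles) {        # maternal allele, 1/2 each
    for (i in seq_len(nrow(pc))) {
      g <- genotype_label(m, pc$s_allele[i])
      out[g] <- out[g] + 0.5 * pc$probability[i]
    }
  }
  out
}

#' Exact multinomial goodness-of-fit p-value
#'
#' Probability, under the multinomial null `prob`, of an outcome at most as
#' probable as the observed one (full enumeration of compositions for totals
#' up to `max_enumerate`, otherwise Monte Carlo with a fixed internal seed).
#' Categories with null probability zero force p = 0 whenever they carry a
#' positive observed count.
#'
#' @param counts Non-negative integer vector.
#' @param prob Null probabilities, same length, summing to 1.
#' @param max_enumerate Largest total for which compositions are enumerated
#'   exactly (default 200).
#' @param n_sim Monte-Carlo draws beyond that (default 1e5).
#' @param seed Seed for the Monte-Carlo branch.
#' @return P-value in \[0, 1\].
#' @export
multinomial_test <- function(counts, prob, max_enumerate = 200,
                             n_sim = 1e5, seed = 20211104) {
  stopifnot(length(counts) == length(prob), all(counts >= 0),
            all(prob >= 0))
  prob <- prob / sum(prob)
  if (any(counts[prob == 0] > 0)) return(0)
  keep <- prob > 0
  counts <- counts[keep]; prob <- prob[keep]
  n <- sum(counts)
  if (n == 0) stop_input("all-zero counts")
  if (length(counts) == 1L) return(1)
  obs <- stats::dmultinom(counts, prob = prob)
  tol <- obs * 1e-7
  if (n <= max_enumerate) {
    comps <- compositions(n, length(counts))
    probs <- apply(comps, 1L, stats::dmultinom, prob = prob)
    sum(probs[probs <= obs + tol])
  } else {
    sims <- with_seed(seed, stats::rmultinom(n_sim, n, prob))
    probs <- apply(sims, 2L, stats::dmultinom, prob = prob)
    mean(probs <= obs + tol)
  }
}

# All ways to write n as an ordered sum of k non-negative integers.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1L), deparse.level = 0)
  })
  do.call(rbind, out)
}

#' Infer a transgene's detoxification specificity from progeny counts
#'
#' Compares the observed self-progeny genotype counts against the predicted
#' distributions under each non-empty target subset of the parental alleles
#' and picks the maximum-multinomial-likelihood model (ties broken toward
#' the smaller target set). An exact multinomial goodness-of-fit p-value is
#' reported for the selected model; `rejected` flags a fit worse than
#' `alpha`.
#'
#' This is the genetic argument used for transgenic lines: e.g. 12 S3/S3L
#' and 9 S3L/S3L self-progeny with no S3/S3 implies only S3L-pollen carrying
#' the transgene was transmitted, so the transgene detoxifies S3L only.
#'
#' @param parent_alleles Length-2 character vector.
#' @param counts Named non-negative counts; names are genotype labels as
#'   produced by [genotype_label()] (e.g. `"S3/S3L"`).
#' @param alpha Significance level for the goodness-of-fit flag.
#' @param transgene_zygosity Passed to [predict_progeny()].
#' @return A list of class `specificity_inference`: `spec` (the selected
#'   [detox_spec()]), `p_value`, `rejected`, `loglik` table,
#'   `breakdown_predicted`.
#' @examples
#' infer_specificity(c("S3", "S3L"),
#'                   c("S3/S3L" = 12, "S3L/S3L" = 9, "S3/S3" = 0))
#' @export
infer_specificity <- function(parent_alleles, counts, alpha = 0.05,
                              transgene_zygosity = "hemizygous") {
  stopifnot(length(parent_alleles) == 2)
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop_input("counts must be non-negative")
  if (sum(counts) == 0) stop_input("all-zero counts")
  a <- sort(unique(parent_alleles))
  valid <- unique(as.vector(outer(a, a, genotype_label)))
  if (length(setdiff(names(counts), valid))) {
    stop_input("genotype labels outside the parental cross: ",
               paste(setdiff(names(counts), valid), collapse = ", "))
  }
  full <- stats::setNames(numeric(length(valid)), valid)
  full[names(counts)] <- counts

  subsets <- if (length(a) == 1L) list(a) else list(a[1], a[2], a)
  fits <- lapply(subsets, function(tg) {
    pred <- predict_progeny(parent_alleles, detox_spec("candidate", tg),
                            transgene_zygosity = transgene_zygosity)
    pred <- pred[names(full)]
    ll <- if (any(full > 0 & pred == 0)) -Inf
          else sum(full[full > 0] * log(pred[full > 0]))
    list(targets = tg, pred = pred, loglik = ll)
  })
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  sizes <- lengths(lapply(fits, `[[`, "targets"))
  best <- order(-ll, sizes)[1L]        # max likelihood, then parsimony

  sel <- fits[[best]]
  p <- multinomial_test(unname(full), unname(sel$pred))
  structure(list(
    spec = detox_spec("inferred", sel$targets, universe = a),
    p_value = p,
    rejected = p < alpha,
    alpha = alpha,
    loglik = data.frame(
      targets = vapply(fits, function(f) paste(f$targets, collapse = ","),
                       character(1)),
      loglik = ll
    ),
    counts = full,
    predicted = sel$pred,
    breakdown_predicted = TRUE
  ), class = "specificity_inference")
}

#' @export
print.specificity_inference <- function(x, ...) {
  cat("Detoxification specificity inference\n")
  cat("  inferred targets : {", paste(x$spec$targets, collapse = ", "),
      "}\n", sep = "")
  cat("  exact multinomial goodness-of-fit p =",
      format(x$p_value, digits = 4),
      if (x$rejected) paste0("(rejected at alpha = ", x$alpha, ")") else "",
      "\n")
  invisible(x)
}

#' Two-sided exact binomial segregation test
#'
#' Tests observed counts of two progeny classes against an expected
#' proportion for the first class.
#'
#' @param counts Length-2 non-negative integer vector.
#' @param ratio Expected proportion of the first class, in (0, 1).
#' @return Two-sided exact binomial p-value.
#' @examples
#' segregation_test(c(12, 9))   # ~0.664
#' @export
segregation_test <- function(counts, ratio = 0.5) {
  stopifnot(length(counts) == 2, all(counts >= 0))
  if (ratio <= 0 || ratio >= 1) stop_input("ratio must be in (0,1)")
  if (sum(counts) == 0) stop_input("zero total count")
  stats::binom.test(counts[1], sum(counts), p = ratio)$p.value
}

#' Population cross-compatibility by exact enumeration
#'
#' Given a haplotype-by-allele detoxification matrix (entry TRUE when the
#' SLF repertoire of the row haplotype detoxifies the column S-RNase),
#' returns the fraction of (pollen haplotype, heterozygous nonself style
#' pair) combinations in which both style S-RNases are detoxified. With
#' independent Bernoulli(PR) entries this converges to PR^2, the closed-form
#' single-SLF style-acceptance rate.
#'
#' @param detox_matrix Square logical matrix with haplotype row/column
#'   names; diagonal must be FALSE (self never detoxified).
#' @return Fraction in \[0, 1\].
#' @export
population_cross_compatibility <- function(detox_matrix) {
  m <- as.matrix(detox_matrix)
  k <- nrow(m)
  if (k < 3 || ncol(m) != k) {
    stop_input("need a square matrix over at least 3 haplotypes")
  }
  if (any(diag(m))) stop_input("diagonal (self) entries must be FALSE")
  tot <- 0L; acc <- 0
  for (h in seq_len(k)) {
    others <- setdiff(seq_len(k), h)
    pairs <- utils::combn(others, 2L)
    tot <- tot + ncol(pairs)
    acc <- acc + sum(m[h, pairs[1L, ]] & m[h, pairs[2L, ]])
  }
  acc / tot
}

#' Read a progeny-count table
#'
#' Expected columns: `line_id`, `parent_genotype` (e.g. `"S3,S3L"`),
#' `genotype` (label as in [genotype_label()]), `count`. Extra columns are
#' preserved.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_progeny_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line_id", "parent_genotype", "genotype", "count")
  if (length(setdiff(need, names(tab)))) {
    stop_input("progeny table must have columns: ",
               paste(need, collapse = ", "))
  }
  tab$count <- as.integer(tab$count)
  tab
}

#' Specificity inference over a whole progeny table
#'
#' Applies [infer_specificity()] per `line_id` of a table read with
#' [read_progeny_counts()].
#'
#' @param tab data.frame from [read_progeny_counts()].
#' @param alpha Significance level.
#' @return data.frame with one row per line: `line_id`, `parent_genotype`,
#'   `inferred_targets`, `p_value`, `breakdown_predicted`.
#' @export
infer_specificity_table <- function(tab, alpha = 0.05) {
  out <- lapply(split(tab, tab$line_id), function(d) {
    parent <- trimws(strsplit(d$parent_genotype[1], ",")[[1]])
    counts <- stats::setNames(d$count, d$genotype)
    fit <- infer_specificity(parent, counts, alpha = alpha)
    data.frame(line_id = d$line_id[1],
               parent_genotype = d$parent_genotype[1],
               inferred_targets = paste(fit$spec$targets, collapse = ","),
               p_value = fit$p_value,
               breakdown_predicted = fit$breakdown_predicted)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$line_id, unique(tab$line_id))), , drop = FALSE]
}
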