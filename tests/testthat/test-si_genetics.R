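# Pollination genetics: compatibility, competitive interaction, progeny
# prediction and specificity inference.

test_that("pollen compatibility follows non-self recognition with transgene override", {
  style <- c("S3", "S3L")
  # self S-RNase undetoxified without a transgene covering it
  expect_false(pollen_compatible("S3", style))
  expect_false(pollen_compatible("S3L", style))
  # transgene covering the self allele rescues only the matching pollen
  tg <- detox_spec("tg", "S3L")
  expect_true(pollen_compatible("S3L", style, tg))
  expect_false(pollen_compatible("S3", style, tg))
  # not carrying the transgene means no rescue
  expect_false(pollen_compatible("S3L", style, tg, carries_transgene = FALSE))
  # nonself pollen from a third haplotype passes via the endogenous network
  expect_true(pollen_compatible("S5", style, universe = c("S3", "S3L", "S5")))
  expect_error(pollen_compatible("S9", style, universe = c("S3", "S3L")),
               "unknown allele")
})

test_that("endogenous repertoire overrides restrict the default network", {
  style <- c("S3", "S3L")
  # an S5 haplotype whose repertoire misses S3 is incompatible
  endo <- list(S5 = detox_spec("S5-repertoire", "S3L"))
  expect_false(pollen_compatible("S5", style, endogenous_specs = endo,
                                 universe = c("S3", "S3L", "S5")))
  expect_error(
    pollen_compatible("S5", style,
                      endogenous_specs = list(S5 = detox_spec("bad", "S5")),
                      universe = c("S3", "S3L", "S5")),
    "own allele")
})

test_that("enlarging transgene targets never breaks compatibility (monotonicity)", {
  universe <- c("S3", "S3L", "S5")
  subsets <- list(character(), "S3", "S3L", c("S3", "S3L"),
                  c("S3", "S5"), universe)
  for (pollen in universe) {
    for (style in list(c("S3", "S3L"), c("S3", "S5"), c("S3L", "S5"))) {
      for (i in seq_along(subsets)) {
        for (j in seq_along(subsets)) {
          if (!all(subsets[[i]] %in% subsets[[j]])) next
          small <- pollen_compatible(pollen, style,
                                     detox_spec("a", subsets[[i]]),
                                     universe = universe)
          big <- pollen_compatible(pollen, style,
                                   detox_spec("b", subsets[[j]]),
                                   universe = universe)
          expect_true(!small || big)
        }
      }
    }
  }
})

test_that("SI breakdown requires a transgene covering a self S-RNase", {
  parent <- c("S3", "S3L")
  expect_false(predict_breakdown(parent, detox_spec("ctrl", character())))
  expect_true(predict_breakdown(parent, detox_spec("slf5", "S3L")))
  expect_true(predict_breakdown(parent, detox_spec("slf6", "S3")))
  expect_true(predict_breakdown(parent, detox_spec("ah", c("S3", "S3L"))))
})

test_that("predicted progeny distributions match pollen-class enumeration", {
  parent <- c("S3", "S3L")
  p1 <- predict_progeny(parent, detox_spec("tg", "S3L"))
  expect_equal(p1[["S3/S3L"]], 0.5)
  expect_equal(p1[["S3L/S3L"]], 0.5)
  expect_equal(p1[["S3/S3"]], 0)

  p2 <- predict_progeny(parent, detox_spec("tg", "S3"))
  expect_equal(p2[["S3/S3"]], 0.5)
  expect_equal(p2[["S3/S3L"]], 0.5)
  expect_equal(p2[["S3L/S3L"]], 0)

  # both targets: all transgenic pollen compatible, Mendelian 1/4:1/2:1/4
  p3 <- predict_progeny(parent, detox_spec("tg", c("S3", "S3L")))
  expect_equal(unname(p3[c("S3/S3", "S3/S3L", "S3L/S3L")]),
               c(0.25, 0.5, 0.25))

  for (p in list(p1, p2, p3)) {
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # homozygous transgene gives the same conditional distribution here
  expect_equal(predict_progeny(parent, detox_spec("tg", "S3L"),
                               transgene_zygosity = "homozygous"), p1)
  expect_error(predict_progeny(parent, detox_spec("none", character())),
               "fully incompatible")
})

test_that("positive predicted progeny genotypes are reachable by a compatible pollen class", {
  parent <- c("S3", "S3L")
  for (targets in list("S3", "S3L", c("S3", "S3L"))) {
    tg <- detox_spec("tg", targets)
    pred <- predict_progeny(parent, tg)
    compat <- Filter(function(a) pollen_compatible(a, parent, tg),
                     unique(parent))
    reachable <- unique(as.vector(outer(parent, compat, genotype_label)))
    expect_setequal(names(pred)[pred > 0], reachable)
  }
})

test_that("specificity inference recovers the target set behind observed ratios", {
  parent <- c("S3", "S3L")
  fit1 <- infer_specificity(parent,
                            c("S3/S3L" = 12, "S3L/S3L" = 9, "S3/S3" = 0))
  expect_equal(fit1$spec$targets, "S3L")
  expect_false(fit1$rejected)

  fit2 <- infer_specificity(parent,
                            c("S3/S3" = 13, "S3/S3L" = 10, "S3L/S3L" = 0))
  expect_equal(fit2$spec$targets, "S3")

  # exact Mendelian 1/4:1/2:1/4 identifies both targets
  fit3 <- infer_specificity(parent,
                            c("S3/S3" = 5, "S3/S3L" = 10, "S3L/S3L" = 5))
  expect_equal(fit3$spec$targets, c("S3", "S3L"))
  expect_equal(fit3$p_value, 1, tolerance = 1e-9)

  expect_error(infer_specificity(parent, c("S3/S3" = 0, "S3/S3L" = 0)),
               "all-zero")
  expect_error(infer_specificity(parent, c("S5/S5" = 3)), "outside")
})

test_that("likelihood ties break toward the smaller target set", {
  # counts in only one homozygote class + het class fit both {S3L} and, worse,
  # {S3,S3L}; a degenerate 0-draw table is impossible, so engineer a tie:
  # single-allele parent has one subset only
  fit <- infer_specificity(c("S3", "S3"), c("S3/S3" = 7))
  expect_equal(fit$spec$targets, "S3")
  expect_equal(fit$p_value, 1)
})

test_that("exact binomial segregation test matches tail summation", {
  expect_equal(segregation_test(c(12, 9)), 0.6636238, tolerance = 1e-6)
  expect_equal(segregation_test(c(10, 10)), 1.0)
  expect_equal(segregation_test(c(20, 0)), 2 * 0.5^20, tolerance = 1e-12)
  expect_error(segregation_test(c(0, 0)), "zero total")
  expect_error(segregation_test(c(3, 4), ratio = 1.2), "ratio")
})

test_that("exact multinomial test reduces to the exact binomial for two classes", {
  expect_equal(multinomial_test(c(12, 9), c(0.5, 0.5)),
               stats::binom.test(12, 21)$p.value, tolerance = 1e-12)
  expect_equal(multinomial_test(c(5, 10, 5), c(0.25, 0.5, 0.25)), 1,
               tolerance = 1e-9)
  # positive count on a zero-probability class is impossible under the model
  expect_equal(multinomial_test(c(3, 10, 8), c(0, 0.5, 0.5)), 0)
  expect_error(multinomial_test(c(0, 0), c(0.5, 0.5)), "all-zero")
})

test_that("population cross-compatibility enumerates style pairs exactly", {
  full <- matrix(TRUE, 4, 4); diag(full) <- FALSE
  expect_equal(population_cross_compatibility(full), 1)
  none <- matrix(FALSE, 4, 4)
  expect_equal(population_cross_compatibility(none), 0)
  expect_error(population_cross_compatibility(matrix(FALSE, 2, 2)),
               "at least 3")
  m <- matrix(TRUE, 3, 3); diag(m) <- FALSE
  m[1, 2] <- FALSE  # H1 pollen fails on the (H2,H3) style
  expect_equal(population_cross_compatibility(m), 2 / 3)
})

test_that("packaged progeny fixture reproduces the per-line conclusions", {
  tab <- read_progeny_counts(fixture_path("progeny_counts.tsv"))
  res <- infer_specificity_table(tab)
  expect_equal(res$inferred_targets[res$line_id == "ShS5-SLF5_line2"], "S3L")
  expect_equal(res$inferred_targets[res$line_id == "ShS5-SLF6_line3"], "S3")
  expect_equal(res$inferred_targets[res$line_id == "AhSLF1_line1"],
               "S3,S3L")
  expect_true(all(res$breakdown_predicted))
})
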