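test_that("similar expression is a strict twofold window", {
  expect_true(classify_similarity(1))
  expect_false(classify_similarity(2))   # |log2| = 1 exactly
  expect_false(classify_similarity(0.5))
  expect_true(classify_similarity(1.99))
  expect_error(classify_similarity(0), "positive")
  expect_error(classify_similarity(-1), "positive")
})

test_that("dosage classes partition the SE band with inner-biased bounds", {
  expect_identical(as.character(assign_dosage_class(c(1, 1.5, 0.6, 1.8))),
                   c("I", "II", "III", "IV"))
  # boundary ties resolve toward the compensated / dosage-sensitive labels
  expect_identical(as.character(assign_dosage_class(c(0.75, 1.25, 1.75))),
                   c("I", "I", "II"))
  expect_error(assign_dosage_class(2.5), "non-SE")

  grid <- 2^seq(-0.999, 0.999, length.out = 4001)
  cls <- assign_dosage_class(grid)
  expect_false(anyNA(cls))
  expect_setequal(as.character(unique(cls)), c("I", "II", "III", "IV"))
})

test_that("the exact binomial DE test matches enumeration and is symmetric", {
  expect_gte(de_exact_test(5, 5, 1e6, 1e6), 0.99)
  expect_equal(de_exact_test(10, 0, 1e6, 1e6), 2 * 0.5^10)
  expect_equal(de_exact_test(0, 0, 1e6, 1e6), 1)

  set.seed(23)
  for (i in 1:50) {
    a <- sample(0:200, 1)
    b <- sample(0:200, 1)
    la <- sample(1e5:1e7, 1)
    lb <- sample(1e5:1e7, 1)
    expect_equal(de_exact_test(a, b, la, lb),
                 de_exact_test(b, a, lb, la), tolerance = 1e-12)
    expect_equal(de_exact_test(a, b, la, lb),
                 oracle_binom_p(a, b, la / (la + lb)), tolerance = 1e-12)
  }
})

test_that("dependent-test FDR follows the harmonic step-up", {
  expect_equal(fdr_adjust_dependent(0.04), 0.04)
  expect_equal(fdr_adjust_dependent(c(0.01, 0.02, 0.03)),
               rep(0.055, 3))
  expect_equal(fdr_adjust_dependent(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust_dependent(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_adjust_dependent(numeric(0)), "empty")
})

test_that("dependent-test FDR agrees with the reference step-up and dominates BH", {
  set.seed(31)
  for (i in 1:40) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    q <- fdr_adjust_dependent(p)
    expect_equal(q, stats::p.adjust(p, method = "BY"))
    expect_true(all(q >= stats::p.adjust(p, method = "BH") - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone step-up
  }
})

test_that("SE and DE flags are computed independently", {
  # a gene can be similarly expressed yet significantly different: a 1.9-fold
  # change on deep counts is inside the SE window but far beyond chance
  ratios <- data.frame(gene_id = c("deep", "shallow"),
                       fold_change = c(1.9, 1.9))
  counts <- data.frame(gene_id = c("deep", "shallow"),
                       count_a = c(1900, 4), count_b = c(1000, 2))
  cls <- classify_dosage(ratios, analysis_config(), counts = counts,
                         libsize_a = 1e6, libsize_b = 1e6)
  expect_true(all(cls$se_flag))
  expect_identical(cls$de_flag, c(TRUE, FALSE))
  expect_identical(cls$de_direction, c("higher", "none"))
  expect_identical(as.character(cls$dosage_class), c("IV", "IV"))
})

test_that("tallies reproduce count/percentage arithmetic", {
  one <- classify_dosage(data.frame(gene_id = "g", fold_change = 1))
  t1 <- tally(one)
  expect_identical(t1$per_class[["I"]], 1L)
  expect_equal(t1$percentages$class_of_se[["I"]], 100)

  # representative fold change per class, replicated to target counts
  fc <- c(I = 1, II = 1.5, III = 0.6, IV = 1.9)
  mk <- function(counts) {
    data.frame(gene_id = seq_len(sum(counts)),
               fold_change = rep(fc[names(counts)], counts))
  }
  juv <- tally(classify_dosage(mk(c(I = 26376, II = 9935, III = 19672,
                                    IV = 2093))))
  expect_identical(juv$n_se, 58076L)
  expect_equal(unname(juv$percentages$class_of_se), c(45, 17, 34, 4))
  liv <- tally(classify_dosage(mk(c(I = 3508, II = 1308, III = 4947,
                                    IV = 305))))
  expect_identical(liv$n_se, 10068L)
  expect_equal(unname(liv$percentages$class_of_se), c(35, 13, 49, 3))
})

test_that("percentages recompute under round-half-away-from-zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(22.45, 1), 22.5)
})
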