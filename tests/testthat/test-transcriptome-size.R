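test_that("Livak genome-normalized ratios follow 2^-ddCq", {
  flat <- make_plate(c(PA = 4, PAA = 4))
  expect_equal(livak_per_genome(flat, "tg", c("rpl8", "eef1a", "actb2"))$
                 ratio_per_genome, 1)

  shifted <- make_plate(c(PA = 4, PAA = 5))
  expect_equal(livak_per_genome(shifted, "tg",
                                c("rpl8", "eef1a", "actb2"))$
                 ratio_per_genome, 0.5)

  study_like <- make_plate(c(PA = 5, PAA = 5.32))
  lv <- livak_per_genome(study_like, "tg", c("rpl8", "eef1a", "actb2"))
  expect_equal(lv$ratio_per_genome, 2^-0.32, tolerance = 1e-9)
  expect_equal(unname(lv$per_genomotype_mean_delta_cq),
               c(5.32, 5.00))
})

test_that("missing wells raise errors naming sample and target", {
  plate <- make_plate(c(PA = 4, PAA = 4))
  no_ref <- plate[!(plate$sample_id == "PA_2" & plate$target == "actb2"), ]
  expect_error(livak_per_genome(no_ref, "tg", c("rpl8", "eef1a", "actb2")),
               "PA_2.*actb2")
  expect_error(livak_per_genome(plate, "absent",
                                c("rpl8", "eef1a", "actb2")),
               "no cDNA wells")
  expect_error(livak_per_genome(plate, "tg", "rpl8",
                                numerator_genomotype = "PAAA"),
               "PAAA")
})

test_that("a constant Cq shift per sample cancels in the normalization", {
  base <- make_plate(c(PA = 4.2, PAA = 3.9))
  shifted <- make_plate(c(PA = 4.2, PAA = 3.9),
                        sample_shift = c(1.5, -0.7, 0.3))
  refs <- c("rpl8", "eef1a", "actb2")
  expect_equal(livak_per_genome(shifted, "tg", refs)$ratio_per_genome,
               livak_per_genome(base, "tg", refs)$ratio_per_genome,
               tolerance = 1e-12)
})

test_that("ploidy scaling and the size quotient compose", {
  expect_equal(per_cell_ratio(0.8, 3, 2), 1.2)
  expect_equal(per_cell_ratio(1.0, 3, 2), 1.5)
  expect_equal(per_cell_ratio(0.6, 3, 2), 0.9)
  expect_equal(size_ratio(1.2, 1.5), 0.8)
  expect_equal(size_ratio(1.2, 1.0), 1.2)
  set.seed(71)
  x <- rlnorm(20)
  expect_equal(size_ratio(x, x), rep(1, 20))
  y <- rlnorm(20)
  expect_equal(size_ratio(x, y) * y, x, tolerance = 1e-12)
  expect_error(size_ratio(1.2, 0), "per_transcriptome_ratio")
})

test_that("the one-sample t-test handles regular and degenerate inputs", {
  expect_equal(one_sample_t(rep(2, 5), 2), list(t = 0, df = 4L,
                                                p_two_sided = 1))
  sz <- c(0.8, 0.9, 1.6, 0.9, 1.2, 0.8)
  vs_null <- one_sample_t(sz, 1.0)
  expect_equal(vs_null$t, 0.26, tolerance = 0.01)
  expect_equal(vs_null$p_two_sided, 0.81, tolerance = 0.01)
  vs_dosage <- one_sample_t(sz, 1.5)
  expect_equal(vs_dosage$t, -3.64, tolerance = 0.01)
  expect_equal(vs_dosage$p_two_sided, 0.015, tolerance = 0.01)
  expect_warning(res <- one_sample_t(rep(2, 4), 1), "zero sample variance")
  expect_equal(res$p_two_sided, 0)
  expect_error(one_sample_t(1, 1), "at least two")
})

test_that("one-sample t p-values match the density-integration oracle", {
  set.seed(73)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), sample(-2:2, 1), runif(1, 0.5, 3))
    mu <- rnorm(1)
    expect_equal(one_sample_t(x, mu)$p_two_sided, oracle_t_p(x, mu),
                 tolerance = 1e-6)
  }
})

test_that("Tukey fences use the hinge quartiles", {
  expect_false(any(tukey_outliers(c(0.8, 0.9, 1.6, 0.9, 1.2, 0.8))))
  expect_false(any(tukey_outliers(rep(3, 6))))
  flags <- tukey_outliers(c(1, 1, 1, 1, 1, 10))
  expect_identical(which(flags), 6L)
  expect_error(tukey_outliers(c(1, 2, 3)), "at least four")
})

test_that("the size estimator composes qPCR and RNA-seq stages", {
  ratios <- c(rpl35 = 0.8, pabpc1a = 1.0, rpsa = 0.5, tga = 1.2,
              tgb = 0.9, tgc = 0.7)
  refs <- c("rpl8", "eef1a", "actb2")
  cfg <- simulation_config(seed = 5,
                           qpcr = list(n_biological = 5, n_technical = 3,
                                       cq_noise_sd = 0,
                                       true_per_genome_ratios = ratios))
  plate <- simulate_qpcr(cfg)
  pa_fpkm <- c(40, 55, 70, 25, 90, 33)
  # per-transcriptome ratio equal to the per-cell ratio => all sizes 1
  pa_tab <- tbl(setNames(pa_fpkm, names(ratios)), genomotype = "PA")
  paa_tab <- tbl(setNames(pa_fpkm * 1.5 * unname(ratios), names(ratios)),
                 genomotype = "PAA")
  # noiseless sizes are all exactly 1, so the dosage-effect t-test sits in
  # its zero-variance branch and warns
  suppressWarnings(
    est <- estimate_transcriptome_size(plate, paa_tab, pa_tab,
                                       names(ratios), refs)
  )
  expect_equal(est$table$per_genome, unname(ratios), tolerance = 1e-9)
  expect_equal(est$table$size, rep(1, 6), tolerance = 1e-9)
  expect_equal(est$mean_size, 1, tolerance = 1e-9)
  expect_false(any(est$outlier_flags))
  expect_lt(est$t_vs_dosage_effect$p_two_sided, 1e-6)

  expect_error(
    estimate_transcriptome_size(plate, paa_tab, pa_tab,
                                c(names(ratios), "ghost"), refs),
    "ghost")
})

test_that("qPCR plate data round-trips through CSV", {
  plate <- make_plate(c(PA = 4, PAA = 3.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_qpcr_csv(plate, path)
  back <- read_qpcr_csv(path)
  expect_equal(back$cq, plate$cq)
  expect_identical(back$sample_id, plate$sample_id)
  bad <- plate
  bad$cq[1] <- -1
  expect_error(write_qpcr_csv(bad, path), "finite and positive")
})
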