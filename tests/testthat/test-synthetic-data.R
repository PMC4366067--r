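test_that("simulation configs are validated", {
  expect_error(simulation_config(class_mixture = c(I = 0.7, II = 0.5)),
               "sum to at most 1")
  expect_error(simulation_config(class_mixture = c(V = 0.5)), "names")
  expect_error(simulation_config(measurement_log2_sd = -0.1),
               "nonnegative")
  expect_error(simulation_config(qpcr = list(n_biological = 5,
                                             n_technical = 0,
                                             cq_noise_sd = 0.1,
                                             true_per_genome_ratios =
                                               c(g = 1))),
               "n_technical")
})

test_that("generation is deterministic and files are byte-identical", {
  cfg <- simulation_config(n_genes = 200, seed = 42)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$tables$PAA$fpkm, s2$tables$PAA$fpkm)
  expect_identical(s1$truth, s2$truth)
  q1 <- simulate_qpcr(cfg)
  q2 <- simulate_qpcr(cfg)
  expect_identical(q1, q2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, q1, d1)
  p2 <- write_simulation(s2, q2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("every gene carries exactly one ground-truth label", {
  sim <- simulate_expression(simulation_config(n_genes = 500, seed = 2))
  expect_identical(nrow(sim$truth), 500L)
  expect_identical(anyDuplicated(sim$truth$gene_id), 0L)
  expect_true(all(sim$truth$label %in%
                    c("additive", "I", "II", "III", "IV",
                      "DE_up", "DE_down", "SE_other")))
  expect_true(all(is.finite(sim$truth$true_fold) &
                    sim$truth$true_fold > 0))
})

test_that("noiseless generation is recovered exactly by the classifier", {
  cfg <- simulation_config(n_genes = 3000, additive_fraction = 0,
                           measurement_log2_sd = 0, seed = 9)
  sim <- simulate_expression(cfg)
  prof <- ratio_profile(sim$tables$PAA, sim$tables$PA)
  cls <- classify_dosage(prof)
  m <- merge(cls, sim$truth, by = "gene_id")
  expect_equal(m$fold_change, m$true_fold, tolerance = 1e-12)
  in_class <- m$label %in% c("I", "II", "III", "IV")
  expect_identical(as.character(m$dosage_class[in_class]),
                   m$label[in_class])
  expect_true(all(m$se_flag[m$label == "SE_other"]))
  expect_false(any(m$se_flag[m$label %in% c("DE_up", "DE_down")]))
})

test_that("derived counts quantize the stored abundance by at most half a fragment", {
  cfg <- simulation_config(n_genes = 300, seed = 13)
  sim <- simulate_expression(cfg)
  tab <- sim$tables$AA
  lib <- cfg$library_sizes[["AA"]]
  implied <- tab$fpkm * tab$length * lib / 1e9
  expect_true(all(abs(tab$count - implied) <= 0.5))
  expect_identical(validate_table(tab), character(0))
})

test_that("noiseless qPCR plates reproduce the configured ratios exactly", {
  ratios <- c(rpl35 = 0.8, actb2 = 0.6, pabpc1a = 1.0)
  cfg <- simulation_config(seed = 8,
                           qpcr = list(n_biological = 4, n_technical = 3,
                                       cq_noise_sd = 0,
                                       true_per_genome_ratios = ratios))
  plate <- simulate_qpcr(cfg)
  refs <- c("rpl8", "eef1a", "actb2")
  for (g in names(ratios)) {
    expect_equal(livak_per_genome(plate, g, refs)$ratio_per_genome,
                 unname(ratios[[g]]), tolerance = 1e-9)
  }
})
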