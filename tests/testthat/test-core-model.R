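test_that("compute_fpkm evaluates the closed formula", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(0, 500, 1e7), 0)
  expect_equal(compute_fpkm(250, 2500, 2e7), 5)
})

test_that("compute_fpkm rejects nonpositive length or total, naming the field", {
  expect_error(compute_fpkm(10, 0, 1e6), "gene_length_bp")
  expect_error(compute_fpkm(10, 1000, 0), "total_mapped_fragments")
  expect_error(compute_fpkm(-1, 1000, 1e6), "fragment_count")
})

test_that("compute_fpkm is linear in count, inverse in length and total", {
  set.seed(41)
  for (i in 1:50) {
    cnt <- sample(1:1e4, 1)
    len <- sample(200:5000, 1)
    tot <- sample(1e5:1e8, 1)
    k <- runif(1, 0.5, 5)
    base <- compute_fpkm(cnt, len, tot)
    expect_equal(compute_fpkm(k * cnt, len, tot), k * base)
    expect_equal(compute_fpkm(cnt, k * len, tot), base / k)
    expect_equal(compute_fpkm(cnt, len, k * tot), base / k)
  }
})

test_that("expression tables round-trip through TSV", {
  set.seed(7)
  n <- 50
  lens <- sample(200:8000, n)
  counts <- sample(0:5000, n)
  counts[3] <- NA
  lens[5] <- NA
  fpkm <- runif(n, 0, 500)
  t1 <- expression_table(sprintf("g%02d", 1:n), fpkm = fpkm, length = lens,
                         count = counts, library_label = "lib-A",
                         genomotype = "PAA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(t1, path)
  t2 <- read_expression_tsv(path, genomotype = "PAA")
  expect_identical(t2$gene_id, t1$gene_id)
  expect_identical(t2$count, t1$count)
  expect_identical(t2$length, t1$length)
  expect_true(all(abs(t2$fpkm - t1$fpkm) <=
                    1e-12 * pmax(abs(t1$fpkm), 1)))
})

test_that("validate_table flags violations by gene and rule", {
  clean <- tbl(c(g1 = 2.5, g2 = 0))
  expect_identical(validate_table(clean), character(0))

  bad <- clean
  bad$fpkm[1] <- -1
  expect_match(validate_table(bad), "g1", all = FALSE)

  # consistent count/length/fpkm passes the cross-check, a perturbed
  # abundance fails it
  tot <- 2e7
  consistent <- expression_table("g1", fpkm = compute_fpkm(120, 1500, tot),
                                 length = 1500, count = 120)
  expect_identical(validate_table(consistent, tot), character(0))
  perturbed <- consistent
  perturbed$fpkm <- perturbed$fpkm * 1.001
  v <- validate_table(perturbed, tot)
  expect_length(v, 1)
  expect_match(v, "g1.*inconsistent")
})

test_that("genomotype labels parse into haplome copies and ploidy", {
  paa <- genomotype("PAA")
  expect_identical(paa$haplome_copies, c(A = 2L, P = 1L))
  expect_identical(paa$ploidy, 3L)
  expect_identical(genomotype("PA")$ploidy, 2L)
  expect_error(genomotype("P0"), "haplome letters")
  expect_error(genomotype("PA", haplome_copies = c(P = 0, A = 0)),
               "copy count")
})

test_that("analysis_config validates thresholds and round-trips YAML", {
  expect_error(analysis_config(class_bounds = c(1.25, 0.75, 1.75)),
               "increasing")
  expect_error(analysis_config(class_bounds = c(0.4, 1.25, 1.75)),
               "SE band")
  expect_error(analysis_config(fdr_alpha = 1.2), "fdr_alpha")
  cfg <- analysis_config(se_log2_threshold = 1.5,
                         class_bounds = c(0.8, 1.2, 1.9),
                         zero_policy = "pseudocount", pseudocount = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_analysis_config(cfg, path)
  expect_equal(read_analysis_config(path), cfg)
  expect_error(read_analysis_config(withr::local_tempfile()), "not found")
})
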