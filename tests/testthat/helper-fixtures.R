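# builders and independent oracles shared by the test files

# tiny expression table from a named abundance vector
tbl <- function(abund, genomotype = "PA", label = genomotype,
                length = NULL, count = NULL) {
  expression_table(names(abund), fpkm = unname(abund), length = length,
                   count = count, library_label = label,
                   genomotype = genomotype)
}

# deterministic qPCR plate: every gDNA reference well sits at `ref_cq`;
# the cDNA target wells sit at ref_cq + delta(genomotype), so the
# per-sample delta-Cq is exactly `delta`
make_plate <- function(delta_by_geno, target = "tg",
                       refs = c("rpl8", "eef1a", "actb2"),
                       n_bio = 3, n_tech = 2, ref_cq = 20,
                       sample_shift = 0) {
  rows <- list()
  for (g in names(delta_by_geno)) {
    for (b in seq_len(n_bio)) {
      sid <- sprintf("%s_%d", g, b)
      shift <- if (length(sample_shift) > 1) sample_shift[b] else sample_shift
      for (r in refs) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, genomotype = g, target = r, template = "gdna",
          replicate = seq_len(n_tech), cq = ref_cq + shift)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, genomotype = g, target = target,
        template = "cdna", replicate = seq_len(n_tech),
        cq = ref_cq + shift + delta_by_geno[[g]])
    }
  }
  do.call(rbind, rows)
}

# two-sided one-sample t p-value by numerical integration of the t density
oracle_t_p <- function(values, null_value) {
  n <- length(values)
  t_stat <- (mean(values) - null_value) / (sd(values) / sqrt(n))
  2 * stats::integrate(function(x) stats::dt(x, n - 1), abs(t_stat), Inf,
                       rel.tol = 1e-10)$value
}

# chi-square(1) upper-tail probability by integrating the density
oracle_chisq_p <- function(stat, df = 1) {
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-10)$value
}

# minimum-likelihood two-sided binomial p by explicit enumeration from
# the mass function written out with choose()
oracle_binom_p <- function(a, b, prob_a) {
  n <- a + b
  if (n == 0) return(1)
  k <- 0:n
  probs <- choose(n, k) * prob_a^k * (1 - prob_a)^(n - k)
  min(1, sum(probs[probs <= probs[a + 1] * (1 + 1e-12)]))
}

# 2x2 chi-square statistic from first principles (expected counts)
oracle_chisq_2x2_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
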