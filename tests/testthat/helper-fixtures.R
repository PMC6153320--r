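# Row builder for DNM record fixtures; defaults give a valid rare coding SNV.
dnm_row <- function(sample_id = "s1", cohort = "case", gene = "GENE1",
                    chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    variant_class = "missense", damaging_votes = 0L,
                    max_maf = 0) {
  data.frame(sample_id = sample_id, cohort = cohort, gene = gene,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_class = variant_class, damaging_votes = damaging_votes,
             max_maf = max_maf, stringsAsFactors = FALSE)
}

dnm_rows <- function(...) do.call(rbind, list(...))

# Quadrature oracle for the per-class Bayes factor: numerically integrates
# the Poisson likelihood over the Gamma prior on the relative risk and
# divides by the null likelihood. Independent of the closed form under test.
bf_quadrature <- function(x, lambda, gamma_bar, beta) {
  marg <- stats::integrate(function(g) {
    stats::dpois(x, lambda * g) * stats::dgamma(g, shape = gamma_bar * beta,
                                                rate = beta)
  }, lower = 0, upper = Inf, rel.tol = 1e-10, abs.tol = 0)$value
  marg / stats::dpois(x, lambda)
}

# Brute-force BH step-up from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
  }
  q
}

# Two-sided Fisher p by full hypergeometric enumeration over the table's
# support at fixed margins.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # query margin
  n <- c + d
  k <- a + c          # set margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force two-sample KS statistic: max CDF gap over the pooled values.
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
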