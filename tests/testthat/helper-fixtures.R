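# Shared fixture builders; everything is generated in code at test time.

two_loci <- function() {
  list(locus_spec("L1", c("A", "G"), 0.4),
       locus_spec("L2", c("C", "T"), 0.3))
}

# tiny genotype/clinical pair with every state of two tri-state loci observed
toy_tables <- function(n = 90, seed = 11) {
  loci <- two_loci()
  plan <- effect_plan(intercept = 0)
  co <- simulate_cohort(loci, plan, n, sex_counts = c(n / 2, n / 2),
                        seed = seed)
  list(
    genotypes = co[c("subject_id", "L1", "L2")],
    clinical = co[c("subject_id", "sex", "age_group", "ses", "meq", "stai")],
    cohort = co
  )
}

# brute-force plug-in MI oracle: direct sum over the joint table
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- unname(rowSums(p)); py <- unname(colSums(p))
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  s
}

# two-sided Fisher oracle: hypergeometric tail enumeration, written
# independently of the package's implementation
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  sum(probs[probs <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# random discrete fixture with bounded level counts
random_discrete <- function(n, levels, seed) {
  withr::with_seed(seed, sample.int(levels, n, replace = TRUE))
}
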