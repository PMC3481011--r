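# Small deterministic fixtures shared across the suite.

# A reduced cohort configuration that keeps the planted structure but runs
# fast; used for structural tests where full statistical power is not the
# point.
# Survival linkage is strengthened relative to the package default so the
# screens keep near-certain power at this reduced sample size; statistical
# behaviour at the standard cohort size is exercised in test-acceptance.R.
small_config <- function(seed = 1L, ...) {
  cohort_config(n_smokers = 120, n_nonsmokers = 120, n_background_genes = 40,
                survival = survival_params(log_hr_per_risk_unit = log(8)),
                seed = seed, ...)
}

# States for a pair with an exact 2x2 table, laid out deterministically.
states_from_table <- function(n11, n10, n01, n00) {
  a <- c(rep(1L, n11 + n10), rep(0L, n01 + n00))
  b <- c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00))
  list(a = a, b = b)
}

# Monte-Carlo sample of the precision z-test's independence null for one
# rule on one table: both state vectors are redrawn iid from their
# empirical marginal frequencies and the error count tallied. Returns the
# mid-p empirical probability of an error count at most as extreme as
# observed (small error = more extreme), the same tail the z-test uses.
mc_null_pvalue <- function(tab, rule, n_draws = 2000) {
  n11 <- tab[1]; n10 <- tab[2]; n01 <- tab[3]; n00 <- tab[4]
  N <- sum(tab)
  pa <- (n11 + n10) / N
  pb <- (n11 + n01) / N
  cells <- list(
    IMP = rbind(c(1, 0)), IMPNOT = rbind(c(1, 1)), NOTIMP = rbind(c(0, 0)),
    NOTIMPNOT = rbind(c(0, 1)), EQV = rbind(c(1, 0), c(0, 1)),
    NEQV = rbind(c(1, 1), c(0, 0))
  )[[rule]]
  count_cell <- function(a, b, ca, cb) sum(a == ca & b == cb)
  eobs <- sum(apply(cells, 1, function(cc) {
    c("1_1" = n11, "1_0" = n10, "0_1" = n01, "0_0" = n00)[[
      paste(cc[1], cc[2], sep = "_")]]
  }))
  am <- matrix(stats::rbinom(N * n_draws, 1, pa), N)
  bm <- matrix(stats::rbinom(N * n_draws, 1, pb), N)
  errcnt <- 0
  for (i in seq_len(nrow(cells))) {
    errcnt <- errcnt + colSums((am == cells[i, 1]) & (bm == cells[i, 2]))
  }
  (sum(errcnt < eobs) + 0.5 * sum(errcnt == eobs)) / n_draws
}

# Random 2x2 tables with mean-dichotomization-like margins (0.3-0.7) and a
# latent-Gaussian dependence, the regime the package's tables come from.
random_dichotomized_table <- function(n_range = c(20, 60)) {
  N <- sample(seq(n_range[1], n_range[2]), 1)
  pa <- stats::runif(1, 0.3, 0.7)
  pb <- stats::runif(1, 0.3, 0.7)
  r <- stats::runif(1, -0.9, 0.9)
  z1 <- stats::rnorm(N); z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(N)
  a <- as.integer(z1 > stats::qnorm(1 - pa))
  b <- as.integer(z2 > stats::qnorm(1 - pb))
  c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}
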