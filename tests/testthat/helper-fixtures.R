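# Shared fixtures, built in code.

# A deterministic toy season: nd days of constant daily GDD.
flat_tt <- function(gdd_per_day, nd) {
  thermal_time_series(rep(gdd_per_day, nd))
}

# A reproducible realistic season (169 days, ~2278 GDD).
season_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cl <- simulate_climate(synth_config(seed = 42))
      cache <<- season_thermal_time(cl)
    }
    cache
  }
})

# Balanced one-way phenotype table with exact genetic sample variance.
balanced_pheno <- function(n_geno, n_rep, sigma_G2, sigma_e2, mu = 10,
                           seed = 1) {
  set.seed(seed)
  g <- stats::rnorm(n_geno)
  g <- (g - mean(g)) / stats::sd(g) * sqrt(sigma_G2)
  ids <- sprintf("G%03d", seq_len(n_geno))
  data.frame(
    genotype_id = rep(ids, each = n_rep),
    rep = rep(seq_len(n_rep), n_geno),
    value = mu + rep(g, each = n_rep) +
      stats::rnorm(n_geno * n_rep, 0, sqrt(sigma_e2))
  )
}

# Small F1 dataset (markers + one trait) for genomic-prediction tests.
small_gp_data <- function(n_geno = 30, n_markers = 51, h2 = 0.8, seed = 7) {
  sc <- synth_config(n_genotypes = n_geno, n_markers = n_markers,
                     n_chromosomes = 17,
                     traits = list(tr = list(mean = 10, sd = 2, h2 = h2)),
                     seed = seed)
  mk <- simulate_f1_genotypes(sc)
  tru <- simulate_trait_architecture(mk, sc)
  ph <- simulate_phenotypes(tru, sc)
  list(markers = mk, truth = tru, pheno = ph, config = sc)
}

# Dense-matrix restricted log-likelihood for the RR-BLUP variance ratio:
# the independent oracle route (no spectral shortcut).
dense_reml_loglik <- function(lambda, y, K) {
  n <- length(y)
  one <- rep(1, n)
  V <- K + lambda * diag(n)
  Vi <- solve(V)
  P <- Vi - (Vi %*% one %*% t(one) %*% Vi) / sum(Vi)
  sg <- as.numeric(t(y) %*% P %*% y) / (n - 1)
  -0.5 * ((n - 1) * log(sg) + as.numeric(determinant(V)$modulus) + log(sum(Vi)))
}
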