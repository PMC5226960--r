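# Synthetic inputs with the statistical structure the analysis assumes:
# an F1 bi-parental marker matrix with Haldane linkage, polygenic trait
# architectures, replicated phenotypes at target heritabilities, and
# Mediterranean growing-season climate calibrated to a target GDD sum.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study population: 116 F1 genotypes x 2 replicates,
#' 2160 informative markers on 17 chromosomes (the apple karyotype), the
#' four simulator parameters with their observed means, SDs and
#' heritabilities (rle_gdd 0.033 +/- 0.003, h2 0.59; in_length 2.02 +/-
#' 0.28 cm, h2 0.86; leaf_area 25.54 +/- 5.99 cm2, h2 0.40; loga_syll
#' -1.25 +/- 1.03, h2 0.72), and a growing season accumulating 2278
#' single-sine GDD between April 15 and September 30.
#'
#' @param n_genotypes,n_reps population size and replicates per genotype.
#' @param n_chromosomes,n_markers,map_length_cm genome layout; markers are
#'   spread as evenly as possible across chromosomes and evenly spaced.
#' @param traits named list; each element a list with `mean`, `sd`
#'   (phenotypic, replicate level) and `h2` (target heritability of
#'   genotype means at `n_reps` replicates).
#' @param genetic_cor genetic correlation matrix between traits (order of
#'   `traits`); default independent.
#' @param gdd_target target cumulative single-sine GDD for the season.
#' @param ar1_rho lag-1 autocorrelation of daily temperature noise.
#' @param seed master seed; all generation is deterministic given it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genotypes = 116L, n_reps = 2L,
                         n_chromosomes = 17L, n_markers = 2160L,
                         map_length_cm = 80,
                         traits = list(
                           rle_gdd = list(mean = 0.033, sd = 0.003, h2 = 0.59),
                           in_length = list(mean = 2.02, sd = 0.28, h2 = 0.86),
                           leaf_area = list(mean = 25.54, sd = 5.99, h2 = 0.40),
                           loga_syll = list(mean = -1.25, sd = 1.03, h2 = 0.72)
                         ),
                         genetic_cor = NULL,
                         gdd_target = 2278,
                         ar1_rho = 0.6,
                         seed = 1L) {
  for (tr in traits) {
    if (tr$sd <= 0) stop("trait SDs must be positive")
    if (tr$h2 <= 0 || tr$h2 > 1) stop("trait h2 must be in (0, 1]")
  }
  if (is.null(genetic_cor)) genetic_cor <- diag(length(traits))
  ev <- eigen(genetic_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic correlation matrix is not positive semi-definite")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_reps = as.integer(n_reps),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_markers = as.integer(n_markers),
                 map_length_cm = map_length_cm,
                 traits = traits, genetic_cor = genetic_cor,
                 gdd_target = gdd_target, ar1_rho = ar1_rho,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate F1 bi-parental marker genotypes with linkage
#'
#' Each marker is heterozygous (A/B) in exactly one randomly assigned parent
#' and homozygous (A/A) in the other, so offspring segregate 1:1 between
#' A/A (+1) and A/B (-1). Within a chromosome, the informative parent's
#' transmitted haplotype follows a two-state recombination process under the
#' Haldane (no-interference) map function: the switch probability between
#' markers `d` cM apart is `(1 - exp(-2d/100)) / 2`. The two parents'
#' gametes are independent.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (defaults to the config's master seed).
#' @return A `marker_data` object with `W` (coded -1/+1), `map` (marker_id,
#'   chromosome, pos_cm, informative_parent) and `parents` (2 x M parental
#'   genotype matrix).
#' @export
simulate_f1_genotypes <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_genotypes
  m_per_chr <- rep(config$n_markers %/% config$n_chromosomes, config$n_chromosomes)
  rem <- config$n_markers %% config$n_chromosomes
  if (rem > 0) m_per_chr[seq_len(rem)] <- m_per_chr[seq_len(rem)] + 1L
  if (any(m_per_chr > 1) && config$map_length_cm <= 0) {
    stop("zero map length with more than one marker per chromosome")
  }
  W <- matrix(0L, n, config$n_markers)
  map <- data.frame(marker_id = character(0), chromosome = integer(0),
                    pos_cm = numeric(0), informative_parent = integer(0))
  col0 <- 0L
  for (chr in seq_len(config$n_chromosomes)) {
    m <- m_per_chr[chr]
    pos <- if (m == 1) 0 else seq(0, config$map_length_cm, length.out = m)
    parent <- sample(1:2, m, replace = TRUE)
    rec <- if (m > 1) (1 - exp(-2 * diff(pos) / 100)) / 2 else numeric(0)
    # two independent gamete mosaics per offspring (one per parent)
    for (p in 1:2) {
      idx <- which(parent == p)
      if (length(idx) == 0) next
      state <- matrix(0L, n, m)
      state[, 1] <- stats::rbinom(n, 1, 0.5)
      if (m > 1) {
        for (j in 2:m) {
          sw <- stats::rbinom(n, 1, rec[j - 1])
          state[, j] <- (state[, j - 1] + sw) %% 2L
        }
      }
      # state 0: parent transmits A (offspring A/A, +1); state 1: B (A/B, -1)
      W[, col0 + idx] <- 1L - 2L * state[, idx, drop = FALSE]
    }
    map <- rbind(map, data.frame(
      marker_id = sprintf("chr%02d_m%04d", chr, seq_len(m)),
      chromosome = chr, pos_cm = pos, informative_parent = parent))
    col0 <- col0 + m
  }
  colnames(W) <- map$marker_id
  rownames(W) <- sprintf("G%03d", seq_len(n))
  parents <- rbind(ifelse(map$informative_parent == 1, "AB", "AA"),
                   ifelse(map$informative_parent == 2, "AB", "AA"))
  colnames(parents) <- map$marker_id
  structure(list(W = W, map = map, parents = parents), class = "marker_data")
}

# Split the phenotypic variance for a target heritability of genotype means:
# h2 = sG / (sG + se/n) with sG + se = sd^2.
.variance_split <- function(sd_p, h2, n) {
  sigma_p2 <- sd_p^2
  sigma_G2 <- h2 * sigma_p2 / (n * (1 - h2) + h2)
  list(sigma_G2 = sigma_G2, sigma_e2 = sigma_p2 - sigma_G2)
}

#' Draw true marker effects and genetic values
#'
#' Polygenic architecture: every marker receives a normal effect (optionally
#' correlated across traits through the Cholesky factor of the genetic
#' correlation matrix). Genetic values `W g` are centered and rescaled so
#' the realized genetic variance across genotypes matches the target implied
#' by each trait's heritability and replicate count. An optional single-QTL
#' mode assigns one large-effect marker a share of the genetic variance
#' before the polygenic background.
#'
#' @param markers a `marker_data` from [simulate_f1_genotypes()].
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param qtl optional list `list(trait =, variance_share =)` for the
#'   single-QTL mode (e.g. one locus explaining 16.9% of a trait's genetic
#'   variance).
#' @return list with `g_true` (M x T effect matrix), `genetic_values`
#'   (N x T, centered), `sigma_G2`, `sigma_e2` (per-trait).
#' @export
simulate_trait_architecture <- function(markers, config, seed = config$seed + 1L,
                                        qtl = NULL) {
  set.seed(seed)
  W <- markers$W
  M <- ncol(W); N <- nrow(W)
  tn <- names(config$traits)
  Z <- matrix(stats::rnorm(M * length(tn)), M, length(tn))
  L <- chol(config$genetic_cor + diag(1e-10, length(tn)))
  g <- Z %*% L  # correlated raw effects
  colnames(g) <- tn
  if (!is.null(qtl)) {
    j <- sample(M, 1)
    k <- match(qtl$trait, tn)
    if (is.na(k)) stop("qtl trait not found: ", qtl$trait)
    # one marker carrying the requested share of the genetic variance
    g[j, k] <- sign(g[j, k]) *
      sqrt(qtl$variance_share / (1 - qtl$variance_share) * sum(g[-j, k]^2) / M) *
      sqrt(M)
  }
  G <- W %*% g
  sigma_G2 <- numeric(length(tn)); sigma_e2 <- numeric(length(tn))
  for (k in seq_along(tn)) {
    split <- .variance_split(config$traits[[k]]$sd, config$traits[[k]]$h2,
                             config$n_reps)
    sigma_G2[k] <- split$sigma_G2; sigma_e2[k] <- split$sigma_e2
    sc <- sqrt(split$sigma_G2) / stats::sd(G[, k])
    g[, k] <- g[, k] * sc
    G[, k] <- (G[, k] - mean(G[, k])) * sc
  }
  names(sigma_G2) <- names(sigma_e2) <- tn
  rownames(G) <- rownames(W)
  list(g_true = g, genetic_values = G,
       sigma_G2 = sigma_G2, sigma_e2 = sigma_e2)
}

#' Generate replicated phenotypes from genetic values
#'
#' `P_ij = mu + G_i + e_ij` with Gaussian residuals whose variance is set
#' from the target heritability and replicate count. With `years = 2`, a
#' fixed year effect and a genotype-by-year interaction component
#' (`P_ijk = mu + A_i + G_j + I_ij + e_ijk`) are added.
#'
#' @param truth the list from [simulate_trait_architecture()].
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param years 1 or 2 experiment years.
#' @param year_effect additive shift of year 2 (same units as each trait;
#'   scalar applied as a multiple of the trait SD).
#' @param interaction_share variance of the interaction component as a
#'   fraction of the genetic variance (two-year mode).
#' @return data frame with columns `genotype_id`, `year`, `rep`, one column
#'   per trait, plus `a_syll = exp(loga_syll)` when that trait is present.
#' @export
simulate_phenotypes <- function(truth, config, seed = config$seed + 2L,
                                years = 1L, year_effect = 0.5,
                                interaction_share = 0.5) {
  set.seed(seed)
  G <- truth$genetic_values
  N <- nrow(G); tn <- colnames(G)
  rows <- expand.grid(rep = seq_len(config$n_reps),
                      genotype_id = rownames(G),
                      year = seq_len(years),
                      stringsAsFactors = FALSE)[, c("genotype_id", "year", "rep")]
  rows <- rows[order(rows$year, rows$genotype_id, rows$rep), ]
  rownames(rows) <- NULL
  out <- rows
  for (k in seq_along(tn)) {
    mu <- config$traits[[k]]$mean
    se <- sqrt(truth$sigma_e2[k])
    gi <- G[rows$genotype_id, k]
    val <- mu + gi + stats::rnorm(nrow(rows), 0, se)
    if (years == 2) {
      sd_p <- config$traits[[k]]$sd
      ival <- matrix(stats::rnorm(N * years, 0,
                                  sqrt(interaction_share * truth$sigma_G2[k])),
                     N, years,
                     dimnames = list(rownames(G), as.character(seq_len(years))))
      val <- val + (rows$year - 1) * year_effect * sd_p +
        ival[cbind(rows$genotype_id, as.character(rows$year))]
    }
    out[[tn[k]]] <- val
  }
  if ("loga_syll" %in% tn) out$a_syll <- exp(out$loga_syll)
  out
}

#' Simulate a growing-season climate series
#'
#' Daily minimum and maximum temperatures over April 15 to September 30
#' from a seasonal Gaussian-bump profile peaking in late July, plus AR(1)
#' day-to-day noise, with an additive offset calibrated by root finding so
#' the cumulative single-sine GDD (base 7, cap 35) hits the configured
#' target within 1%. The `early_warmth` argument adds a warm pulse over the
#' first month, emulating a year whose thermal time accumulates faster
#' after budburst.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed.
#' @param gdd_target target cumulative GDD (defaults to the config's).
#' @param early_warmth degrees C added at the season start, decaying over
#'   about three weeks.
#' @param year calendar year for the dates.
#' @param noise_sd SD of the AR(1) daily noise (degrees C).
#' @param diurnal_range mean tmax - tmin (degrees C).
#' @return a [climate_series()].
#' @export
simulate_climate <- function(config, seed = config$seed + 3L,
                             gdd_target = config$gdd_target,
                             early_warmth = 0, year = 2007,
                             noise_sd = 1.5, diurnal_range = 11) {
  set.seed(seed)
  start <- as.Date(sprintf("%d-04-15", year))
  end <- as.Date(sprintf("%d-09-30", year))
  nd <- as.integer(end - start) + 1L
  d <- seq_len(nd)
  peak <- as.integer(as.Date(sprintf("%d-07-28", year)) - start) + 1L
  shape <- 9 * exp(-0.5 * ((d - peak) / 75)^2) +
    early_warmth * exp(-0.5 * ((d - 1) / 20)^2)
  eps <- numeric(nd)
  innov <- stats::rnorm(nd, 0, noise_sd * sqrt(1 - config$ar1_rho^2))
  eps[1] <- stats::rnorm(1, 0, noise_sd)
  for (i in 2:nd) eps[i] <- config$ar1_rho * eps[i - 1] + innov[i]
  range_d <- pmax(4, diurnal_range + stats::rnorm(nd, 0, 1.5))
  base_mean <- shape + eps  # before the calibrated offset
  params <- thermal_time_params()
  gdd_of <- function(offset) {
    tm <- base_mean + offset
    sum(daily_gdd_single_sine(tm - range_d / 2, tm + range_d / 2, params))
  }
  f <- function(offset) gdd_of(offset) - gdd_target
  lo <- -5; hi <- 40
  if (f(hi) < 0) stop("GDD target unattainable within the offset bounds")
  offset <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  got <- gdd_of(offset)
  if (abs(got - gdd_target) > 0.01 * gdd_target) {
    stop("calibration failed: reached ", round(got), " GDD for target ", gdd_target)
  }
  tmean <- base_mean + offset
  climate_series(seq(start, end, by = "day"),
                 tmin = tmean - range_d / 2, tmax = tmean + range_d / 2,
                 tmean = tmean)
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates the generator: markers, trait architecture, replicated
#' phenotypes, and two climate presets — a season accumulating the target
#' GDD with a warm start, and a slightly cooler season (98% of the target)
#' with a warmer summer, emulating two contrasting experiment years.
#'
#' @param config a [synth_config()].
#' @param qtl optional single-QTL specification (see
#'   [simulate_trait_architecture()]).
#' @return list with `markers`, `truth`, `phenotypes`, `climates` (named
#'   list `exp1`, `exp2`), `config`.
#' @export
generate_synthetic_dataset <- function(config = synth_config(), qtl = NULL) {
  markers <- simulate_f1_genotypes(config, seed = config$seed)
  truth <- simulate_trait_architecture(markers, config, seed = config$seed + 1L,
                                       qtl = qtl)
  phenotypes <- simulate_phenotypes(truth, config, seed = config$seed + 2L)
  climates <- list(
    exp1 = simulate_climate(config, seed = config$seed + 3L,
                            gdd_target = config$gdd_target,
                            early_warmth = 4, year = 2007),
    exp2 = simulate_climate(config, seed = config$seed + 4L,
                            gdd_target = 0.98 * config$gdd_target,
                            early_warmth = 0, year = 2004)
  )
  list(markers = markers, truth = truth, phenotypes = phenotypes,
       climates = climates, config = config)
}

#' Write a synthetic dataset to CSV files (plus provenance JSON)
#'
#' Emits the three pipeline inputs — climate tables, the marker matrix with
#' its map, and the replicate-level phenotype table — and a provenance file
#' recording the configuration and seed.
#'
#' @param ds the list from [generate_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_climate_csv(ds$climates$exp1, file.path(dir, "climate_exp1.csv"))
  write_climate_csv(ds$climates$exp2, file.path(dir, "climate_exp2.csv"))
  geno <- data.frame(genotype_id = rownames(ds$markers$W), ds$markers$W,
                     check.names = FALSE)
  utils::write.csv(geno, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(ds$markers$map, file.path(dir, "map.csv"), row.names = FALSE)
  utils::write.csv(ds$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  prov <- list(config = unclass(ds$config), generated = "synthetic dataset")
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
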