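# Variance components, broad-sense heritability with exact F-based
# confidence intervals, and trait correlations, for balanced designs
# (the study design: 2 replicates per genotype, optionally 2 years).

# Check the table is balanced for `trait` and return a clean subset.
.check_balanced <- function(table, trait, need_year = FALSE) {
  if (!trait %in% names(table)) stop("trait column not found: ", trait)
  cols <- c("genotype_id", if (need_year) "year", trait)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  x <- table[stats::complete.cases(table[, cols]), cols]
  if (need_year) {
    tab <- table(x$genotype_id, x$year)
    if (length(unique(as.vector(tab))) != 1) {
      stop("unbalanced design: replicate counts differ across genotype x year cells")
    }
  } else {
    tab <- table(x$genotype_id)
    if (length(unique(as.vector(tab))) != 1) {
      stop("unbalanced design: replicate counts differ across genotypes")
    }
  }
  x
}

#' One-way variance components for a balanced design
#'
#' Method-of-moments (ANOVA) estimators for the balanced one-way random
#' model `P_ij = mu + G_i + e_ij`: the residual variance is the within-
#' genotype mean square, and the genotypic variance is
#' `(MS_between - MS_within) / n`, truncated at zero. For balanced data
#' these coincide with the REML estimates whenever the untruncated genotypic
#' component is nonnegative.
#'
#' @param table phenotype data frame: columns `genotype_id` and one column
#'   per trait (replicate-level rows).
#' @param trait name of the trait column.
#' @return list with `sigma_G2`, `sigma_e2`, `n` (replicates), `n_genotypes`,
#'   `ms_between`, `ms_within`, `df_between`, `df_within`.
#' @export
variance_components_oneway <- function(table, trait) {
  x <- .check_balanced(table, trait)
  g <- factor(x$genotype_id)
  y <- x[[trait]]
  ng <- nlevels(g)
  if (ng < 2) stop("need at least 2 genotypes")
  n <- length(y) / ng
  if (n < 2) stop("n = 1 replicate: residual variance unidentifiable")
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  ss_b <- n * sum((gm - grand)^2)
  ss_w <- sum((y - gm[g])^2)
  df_b <- ng - 1
  df_w <- ng * (n - 1)
  msb <- ss_b / df_b
  msw <- ss_w / df_w
  list(sigma_G2 = max(0, (msb - msw) / n), sigma_e2 = msw,
       n = n, n_genotypes = ng,
       ms_between = msb, ms_within = msw,
       df_between = df_b, df_within = df_w)
}

#' Broad-sense heritability (single year)
#'
#' `h2 = sigma_G2 / (sigma_G2 + sigma_e2 / n)`: the heritability of genotype
#' means with `n` replicates. The 95% confidence interval uses the exact
#' F-quantile construction for balanced one-way designs: with
#' `F = MS_between / MS_within`, the bounds are
#' `1 - qF(upper) / F` and `1 - qF(lower) / F`, truncated to `[0, 1]`.
#' The interval requires the design dimensions; pass the result of
#' [variance_components_oneway()] directly, or supply `n_genotypes`.
#'
#' @param sigma_G2 genotypic variance, or the list returned by
#'   [variance_components_oneway()].
#' @param sigma_e2 residual variance (ignored when a list is given).
#' @param n replicates per genotype (ignored when a list is given).
#' @param n_genotypes number of genotypes (for the CI; optional otherwise).
#' @param conf confidence level (default 0.95).
#' @return An object of class `heritability_result`: list with `h2`,
#'   `ci_low`, `ci_high`, `sigma_G2`, `sigma_e2`, `n`, `a = 1`.
#' @export
heritability_single <- function(sigma_G2, sigma_e2 = NULL, n = NULL,
                                n_genotypes = NULL, conf = 0.95) {
  f_obs <- NULL; df1 <- NULL; df2 <- NULL
  if (is.list(sigma_G2)) {
    vc <- sigma_G2
    sigma_e2 <- vc$sigma_e2; n <- vc$n; n_genotypes <- vc$n_genotypes
    f_obs <- vc$ms_between / vc$ms_within
    df1 <- vc$df_between; df2 <- vc$df_within
    sigma_G2 <- vc$sigma_G2
  }
  if (sigma_G2 < 0 || sigma_e2 < 0) stop("variance components must be >= 0")
  if (sigma_G2 == 0 && sigma_e2 == 0) {
    warning("both variance components are zero; heritability undefined")
    return(structure(list(h2 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          sigma_G2 = 0, sigma_e2 = 0, n = n, a = 1),
                     class = "heritability_result"))
  }
  h2 <- sigma_G2 / (sigma_G2 + sigma_e2 / n)
  ci <- c(NA_real_, NA_real_)
  if (is.null(f_obs) && !is.null(n_genotypes)) {
    # reconstruct the F-ratio from untruncated moments (exact when the
    # between mean square exceeded the within one)
    df1 <- n_genotypes - 1; df2 <- n_genotypes * (n - 1)
    if (sigma_e2 > 0) f_obs <- (n * sigma_G2 + sigma_e2) / sigma_e2
  }
  if (!is.null(f_obs) && is.finite(f_obs)) {
    alpha <- 1 - conf
    ci <- c(1 - stats::qf(1 - alpha / 2, df1, df2) / f_obs,
            1 - stats::qf(alpha / 2, df1, df2) / f_obs)
    ci <- pmin(pmax(ci, 0), 1)
  }
  structure(list(h2 = h2, ci_low = ci[1], ci_high = ci[2],
                 sigma_G2 = sigma_G2, sigma_e2 = sigma_e2, n = n, a = 1),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("<heritability_result> h2 = ", round(x$h2, 3), sep = "")
  if (!is.na(x$ci_low)) cat(" (", round(x$ci_low, 3), ", ",
                            round(x$ci_high, 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-way variance components (year fixed, genotype random)
#'
#' Method-of-moments estimators for the balanced mixed model
#' `P_ijk = mu + A_i + G_j + I_ij + e_ijk` with `a` years (fixed), genotype
#' and year-by-genotype interaction random. Expected mean squares give
#' `sigma_e2 = MS_error`, `sigma_I2 = (MS_interaction - MS_error) / n`,
#' `sigma_G2 = (MS_genotype - MS_interaction) / (a n)`, truncated at zero.
#' The fixed year effect is tested against the interaction mean square.
#'
#' @param table phenotype data frame with columns `genotype_id`, `year`
#'   and the trait column; replicate-level rows, both years balanced.
#' @param trait trait column name.
#' @return list with the three components, design dimensions, mean squares,
#'   and `year_f`, `year_p` for the year-effect F-test.
#' @export
variance_components_twoway <- function(table, trait) {
  x <- .check_balanced(table, trait, need_year = TRUE)
  g <- factor(x$genotype_id); yr <- factor(x$year)
  a <- nlevels(yr)
  if (a != 2) stop("two-year analysis requires exactly 2 years (got ", a, ")")
  y <- x[[trait]]
  ng <- nlevels(g)
  n <- length(y) / (ng * a)
  if (n < 2) stop("n = 1 replicate per cell: residual variance unidentifiable")
  grand <- mean(y)
  mg <- tapply(y, g, mean)
  ma <- tapply(y, yr, mean)
  cell <- tapply(y, list(g, yr), mean)
  ss_g <- a * n * sum((mg - grand)^2)
  ss_a <- ng * n * sum((ma - grand)^2)
  ss_i <- n * sum((sweep(sweep(cell, 1, mg), 2, ma) + grand)^2)
  ss_e <- sum((y - cell[cbind(g, yr)])^2)
  df_g <- ng - 1; df_a <- a - 1; df_i <- (a - 1) * (ng - 1)
  df_e <- a * ng * (n - 1)
  ms_g <- ss_g / df_g; ms_a <- ss_a / df_a; ms_i <- ss_i / df_i
  ms_e <- ss_e / df_e
  year_f <- ms_a / ms_i
  list(sigma_G2 = max(0, (ms_g - ms_i) / (a * n)),
       sigma_I2 = max(0, (ms_i - ms_e) / n),
       sigma_e2 = ms_e,
       n = n, a = a, n_genotypes = ng,
       ms_genotype = ms_g, ms_interaction = ms_i, ms_error = ms_e,
       df_genotype = df_g, df_interaction = df_i, df_error = df_e,
       year_f = year_f, year_p = stats::pf(year_f, df_a, df_i, lower.tail = FALSE))
}

#' Broad-sense heritability over two years
#'
#' `h2 = sigma_G2 / (sigma_G2 + sigma_I2 / a + sigma_e2 / (n a))`. The 95%
#' CI uses the same exact F construction as the single-year case, on the
#' genotype-to-interaction mean-square ratio, whose complement-reciprocal is
#' exactly this heritability.
#'
#' @param vc the list returned by [variance_components_twoway()].
#' @param conf confidence level.
#' @return A `heritability_result` (with `sigma_I2` and `a` filled).
#' @export
heritability_two_year <- function(vc, conf = 0.95) {
  h2 <- vc$sigma_G2 /
    (vc$sigma_G2 + vc$sigma_I2 / vc$a + vc$sigma_e2 / (vc$n * vc$a))
  f_obs <- vc$ms_genotype / vc$ms_interaction
  alpha <- 1 - conf
  ci <- c(1 - stats::qf(1 - alpha / 2, vc$df_genotype, vc$df_interaction) / f_obs,
          1 - stats::qf(alpha / 2, vc$df_genotype, vc$df_interaction) / f_obs)
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(h2 = h2, ci_low = ci[1], ci_high = ci[2],
                 sigma_G2 = vc$sigma_G2, sigma_I2 = vc$sigma_I2,
                 sigma_e2 = vc$sigma_e2, n = vc$n, a = vc$a),
            class = "heritability_result")
}

#' Phenotypic and genetic trait correlations
#'
#' Phenotypic correlations are Pearson correlations of replicate-level
#' values. Genetic correlations are Pearson correlations of per-genotype
#' BLUP-style values: centered genotype means shrunken by the trait's
#' heritability of means (`method = "blup"`), or raw genotype means
#' (`method = "means"`). Significance by Pearson's test ([stats::cor.test()]).
#'
#' @param table phenotype data frame (replicate-level, balanced).
#' @param traits character vector of trait column names (>= 2).
#' @param level `"phenotypic"` or `"genetic"`.
#' @param method genotype-value construction for the genetic level.
#' @return list with matrices `r` and `p`, plus `level` and `n`.
#' @export
trait_correlations <- function(table, traits,
                               level = c("phenotypic", "genetic"),
                               method = c("blup", "means")) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (length(traits) < 2) stop("need at least 2 traits")
  if (length(unique(table$genotype_id)) < 3) stop("need at least 3 genotypes")
  for (tr in traits) {
    if (stats::var(table[[tr]], na.rm = TRUE) == 0) {
      stop("zero-variance trait: ", tr)
    }
  }
  vals <- if (level == "phenotypic") {
    table[, traits, drop = FALSE]
  } else {
    g <- factor(table$genotype_id)
    as.data.frame(lapply(traits, function(tr) {
      m <- tapply(table[[tr]], g, mean)
      if (method == "means") return(as.numeric(m))
      vc <- variance_components_oneway(table, tr)
      h2 <- heritability_single(vc)$h2
      as.numeric(h2 * (m - mean(m)))
    }), col.names = traits)
  }
  k <- length(traits)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- stats::cor.test(vals[[i]], vals[[j]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, level = level, n = nrow(vals))
}

#' Heritability report across traits
#'
#' Convenience wrapper mirroring a per-trait summary table: mean, SD,
#' heritability and its confidence interval for each trait.
#'
#' @param table replicate-level phenotype data frame.
#' @param traits trait column names.
#' @return data frame with one row per trait.
#' @export
heritability_report <- function(table, traits) {
  rows <- lapply(traits, function(tr) {
    vc <- variance_components_oneway(table, tr)
    h <- heritability_single(vc)
    data.frame(trait = tr, mean = mean(table[[tr]]), sd = stats::sd(table[[tr]]),
               h2 = h$h2, ci_low = h$ci_low, ci_high = h$ci_high,
               sigma_G2 = vc$sigma_G2, sigma_e2 = vc$sigma_e2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
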