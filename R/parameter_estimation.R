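# Estimation of the four simulator parameters from observations:
# RLE_GDD by regression of leaf counts on cumulative thermal time, the
# branching coefficient by a closed-form inversion of the expected sylleptic
# count, model selection for the leaf-emergence-rate model by BIC, and the
# (r_k, n_days) grid search against a pooled sylleptic profile.

#' Estimate the leaf emergence rate per growing degree-day
#'
#' Ordinary least-squares slope, per genotype, of the cumulative leaf count
#' on cumulative thermal time at the observation days. Regressing cumulative
#' counts on cumulative GDD is equivalent to the slope between thermal time
#' and number of emitted leaves, and avoids the noise of differencing.
#'
#' @param records data frame with columns `genotype_id`, `day` (season-day
#'   index into `tt`, 1-based) and `count` (cumulative leaf count,
#'   nondecreasing within genotype).
#' @param tt a `thermal_time_series` (single-sine accumulation is the
#'   convention used for this trait).
#' @return data frame with columns `genotype_id`, `rle_gdd`.
#' @export
estimate_rle_gdd <- function(records, tt) {
  need <- c("genotype_id", "day", "count")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$day < 1 | records$day > length(tt$cumulative))) {
    stop("observation day outside the thermal-time series")
  }
  split_rec <- split(records, records$genotype_id)
  res <- lapply(names(split_rec), function(g) {
    r <- split_rec[[g]]
    if (nrow(r) < 2) stop("genotype ", g, " has fewer than 2 observation days")
    if (is.unsorted(r$count[order(r$day)])) {
      stop("cumulative counts must be nondecreasing (genotype ", g, ")")
    }
    x <- tt$cumulative[r$day]
    if (stats::var(x) == 0) {
      stop("all observation days share one cumulative-TT value (genotype ", g, ")")
    }
    slope <- stats::cov(x, r$count) / stats::var(x)
    data.frame(genotype_id = g, rle_gdd = slope)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Closed-form estimate of the sylleptic branching coefficient
#'
#' Inverts the expected total sylleptic count: each day from the day `d_b`
#' the node of rank `r_k` appears until season end `d_e`, the expected
#' number of eligibility events is the leaf emission rate
#' (`rle_gdd * TT_d`), each firing with probability
#' `a_syll * rle_gdd * windowmean(TT)`. Hence
#' `a_syll = n_syll / (rle_gdd^2 * sum_d windowmean(TT, d) * TT_d)`.
#'
#' @param n_syll observed total number of sylleptic laterals on the tree.
#' @param rle_gdd the genotype's leaf emergence rate (leaves/GDD), > 0.
#' @param tt a `thermal_time_series` over the growing season.
#' @param branching a [branching_params()]; its `n_days` window convention
#'   matches the simulator's.
#' @param n_preformed preformed metamer count used to locate `d_b`.
#' @return the estimated coefficient, or `NA` (with a warning) when rank
#'   `r_k` is never reached within the season.
#' @export
estimate_a_syll <- function(n_syll, rle_gdd, tt,
                            branching = branching_params(),
                            n_preformed = 8L) {
  if (rle_gdd <= 0) stop("rle_gdd must be positive")
  if (n_syll < 0) stop("n_syll must be nonnegative")
  d_b <- .rank_emergence_day(rle_gdd, tt, branching$r_k, n_preformed)
  if (is.na(d_b)) {
    warning("rank r_k never reached within the season; a_syll undefined")
    return(NA_real_)
  }
  d_e <- length(tt$tt_d)
  denom <- a_syll_denominator(rle_gdd, tt, branching, d_b, d_e)
  if (denom == 0) stop("denominator is zero: no thermal-time accumulation after d_b")
  n_syll / denom
}

# Day on which the node of rank `rank` appears (season-day index; 1 if the
# rank is preformed), or NA if never reached.
.rank_emergence_day <- function(rle_gdd, tt, rank, n_preformed = 8L) {
  if (rank <= n_preformed) return(1L)
  need_neo <- rank - n_preformed
  hit <- which(floor(rle_gdd * tt$cumulative) >= need_neo)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

#' Denominator of the branching-coefficient inversion
#'
#' `rle_gdd^2 * sum_{d = d_b}^{d_e} windowmean(TT, d, n_days) * TT_d`, with
#' the same zero-padded `n_days` window convention as the simulator.
#'
#' @inheritParams estimate_a_syll
#' @param d_b,d_e first and last season day of the summation.
#' @return numeric scalar.
#' @export
a_syll_denominator <- function(rle_gdd, tt, branching = branching_params(),
                               d_b = 1L, d_e = length(tt$tt_d)) {
  s <- 0
  for (d in d_b:d_e) {
    wm <- sum(.window_values(tt$tt_d, d, branching$n_days)) / branching$n_days
    s <- s + wm * tt$tt_d[d]
  }
  rle_gdd^2 * s
}

#' Select a leaf-emergence-rate model by BIC
#'
#' Fits four candidate linear models to interval leaf-emergence rates
#' (leaves/day, computed between consecutive observation days) and returns
#' the minimum-BIC fit:
#' \describe{
#'   \item{m1}{constant rate;}
#'   \item{m2}{constant rate with a genotype effect;}
#'   \item{m3}{rate proportional to daily thermal time by the daily-mean
#'     method (common slope);}
#'   \item{m4}{rate proportional to daily thermal time by the single-sine
#'     method, with a per-genotype slope.}
#' }
#' The candidates span the two contrasts of interest: temperature in or out
#' of the model, and genotype-specific response in or out.
#' `BIC = -2 logL + k log(N)` via [stats::BIC()].
#'
#' @param records data frame with columns `genotype_id`, `day`, `count`
#'   (cumulative), at several days per genotype.
#' @param climate a [climate_series()] covering the observation window.
#' @param params_mean,params_sine threshold parameters for the two
#'   accumulation methods.
#' @return An object of class `rle_model_fit`: list with `model_id`, `fit`
#'   (the selected `lm`), `bic` (named vector over candidates), and
#'   `slopes` (per-genotype slopes for m4, else `NULL`).
#' @export
select_rle_model <- function(records, climate,
                             params_mean = thermal_time_params(method = "mean"),
                             params_sine = thermal_time_params()) {
  if (length(unique(records$genotype_id)) < 1) stop("no genotypes in records")
  tt_mean <- season_thermal_time(climate, params_mean)
  tt_sine <- season_thermal_time(climate, params_sine)
  split_rec <- split(records, records$genotype_id)
  rows <- lapply(names(split_rec), function(g) {
    r <- split_rec[[g]][order(split_rec[[g]]$day), ]
    if (nrow(r) < 2) return(NULL)
    i <- seq_len(nrow(r) - 1)
    dd <- r$day[i + 1] - r$day[i]
    data.frame(
      genotype_id = g,
      rle = (r$count[i + 1] - r$count[i]) / dd,
      tt_mean = (tt_mean$cumulative[r$day[i + 1]] - tt_mean$cumulative[r$day[i]]) / dd,
      tt_sine = (tt_sine$cumulative[r$day[i + 1]] - tt_sine$cumulative[r$day[i]]) / dd
    )
  })
  dat <- do.call(rbind, rows)
  if (is.null(dat) || nrow(dat) < 3) stop("not enough observation intervals to fit models")
  dat$genotype_id <- factor(dat$genotype_id)
  single_geno <- nlevels(dat$genotype_id) < 2
  fits <- list(
    m1 = stats::lm(rle ~ 1, data = dat),
    m2 = if (single_geno) NULL else stats::lm(rle ~ genotype_id, data = dat),
    m3 = stats::lm(rle ~ 0 + tt_mean, data = dat),
    m4 = if (single_geno) stats::lm(rle ~ 0 + tt_sine, data = dat)
         else stats::lm(rle ~ 0 + tt_sine:genotype_id, data = dat)
  )
  fits <- Filter(Negate(is.null), fits)
  singular <- vapply(fits, function(f) anyNA(stats::coef(f)), logical(1))
  bic <- vapply(fits, stats::BIC, numeric(1))
  best <- names(bic)[which.min(bic)]
  slopes <- NULL
  if (best == "m4" && !single_geno) {
    co <- stats::coef(fits$m4)
    slopes <- data.frame(
      genotype_id = sub("^tt_sine:genotype_id", "", names(co)),
      slope = unname(co)
    )
  }
  structure(list(model_id = best, fit = fits[[best]], bic = bic,
                 singular = singular, slopes = slopes, data = dat),
            class = "rle_model_fit")
}

#' @export
print.rle_model_fit <- function(x, ...) {
  cat("<rle_model_fit> selected ", x$model_id, " (BIC ",
      round(x$bic[x$model_id], 2), ")\n", sep = "")
  print(round(x$bic, 2))
  invisible(x)
}

#' Grid search for the branching-rule parameters
#'
#' For every combination of `r_k` and `n_days` on the grid, simulates the
#' population and computes the rank-wise RMSE between the simulated and the
#' observed frequency profile of sylleptic laterals along the trunk (pooled
#' over genotypes). Returns all cells and the argmin; ties are broken toward
#' the smallest `r_k`, then the smallest `n_days`.
#'
#' @param observed_profile data frame with columns `rank` and `freq`
#'   (fraction of trees with a sylleptic lateral at that rank).
#' @param param_table per-genotype parameters (see [simulate_population()]).
#' @param tt a `thermal_time_series`.
#' @param seed master seed; each grid cell uses an offset derived from it.
#' @param r_k_grid,n_days_grid candidate values (defaults 5/10/15/20 and
#'   3/7/10).
#' @param n_reps replicate trees per genotype per cell.
#' @return An object of class `grid_search_result`: list with `grid` (data
#'   frame: r_k, n_days, rmse) and `best` (list with r_k, n_days, rmse).
#' @export
grid_search_branching <- function(observed_profile, param_table, tt, seed = 1L,
                                  r_k_grid = c(5L, 10L, 15L, 20L),
                                  n_days_grid = c(3L, 7L, 10L),
                                  n_reps = 5L) {
  if (is.null(observed_profile) || nrow(observed_profile) == 0) {
    stop("observed profile is empty")
  }
  max_rank <- max(observed_profile$rank)
  obs <- numeric(max_rank)
  obs[observed_profile$rank] <- observed_profile$freq
  cells <- expand.grid(n_days = n_days_grid, r_k = r_k_grid)[, c("r_k", "n_days")]
  rmse <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    br <- branching_params(cells$r_k[i], cells$n_days[i])
    pop <- simulate_population(param_table, br, tt, n_reps = n_reps,
                               seed = seed + (i - 1L) * 100003L)
    prof <- sylleptic_distribution(pop, max_rank)
    rmse[i] <- sqrt(mean((prof$freq - obs)^2))
  }
  grid <- data.frame(r_k = cells$r_k, n_days = cells$n_days, rmse = rmse)
  ord <- order(grid$rmse, grid$r_k, grid$n_days)
  b <- grid[ord[1], ]
  structure(list(grid = grid,
                 best = list(r_k = b$r_k, n_days = b$n_days, rmse = b$rmse),
                 seed = seed),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("<grid_search_result> best (r_k = ", x$best$r_k, ", n_days = ",
      x$best$n_days, "), RMSE ", signif(x$best$rmse, 4), "\n", sep = "")
  invisible(x)
}

#' Write a grid-search report to CSV
#'
#' @param result a `grid_search_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_search_csv <- function(result, path) {
  utils::write.csv(result$grid, path, row.names = FALSE)
  invisible(path)
}
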