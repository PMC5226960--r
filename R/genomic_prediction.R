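# RR-BLUP genomic prediction: all markers fitted as random effects with a
# common variance, REML estimation of the variance ratio by spectral
# decomposition, rescaling of effects to the phenotypic scale, and k-fold /
# leave-one-out cross-validation with genotype-wise folds.

#' Read a marker matrix (and optional linkage map) from CSV
#'
#' Genotype CSV: first column `genotype_id`, remaining columns one marker
#' each, entries in \{-1, +1\} (-1 = heterozygote A/B, +1 = homozygote A/A;
#' markers segregate 1:1 in the F1 cross because each is heterozygous in
#' exactly one parent). Map CSV (optional): columns `marker_id`,
#' `chromosome`, `pos_cm`, and optionally `informative_parent`.
#'
#' @param geno_path path to the genotype CSV.
#' @param map_path optional path to the map CSV.
#' @return An object of class `marker_data`: list with `W` (genotype x
#'   marker matrix) and `map` (data frame or `NULL`).
#' @export
read_marker_csv <- function(geno_path, map_path = NULL) {
  x <- utils::read.csv(geno_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(x)[1] != "genotype_id") stop("first column must be genotype_id")
  W <- as.matrix(x[, -1, drop = FALSE])
  rownames(W) <- x$genotype_id
  if (!all(W %in% c(-1, 1))) stop("marker codes must be -1 or +1")
  map <- NULL
  if (!is.null(map_path)) {
    map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
    need <- c("marker_id", "chromosome", "pos_cm")
    miss <- setdiff(need, names(map))
    if (length(miss)) stop("map CSV missing column(s): ", paste(miss, collapse = ", "))
    if (!identical(map$marker_id, colnames(W))) {
      stop("map marker order does not match genotype columns")
    }
    bad <- unlist(tapply(map$pos_cm, map$chromosome,
                         function(p) is.unsorted(p)), use.names = FALSE)
    if (any(bad)) stop("map positions must be nondecreasing within chromosome")
  }
  structure(list(W = W, map = map), class = "marker_data")
}

#' Keep markers heterozygous in exactly one parent
#'
#' In an F1 bi-parental design only loci heterozygous in a single parent
#' segregate informatively 1:1 and support the two-level \{-1, +1\} coding;
#' loci heterozygous in both or neither parent are dropped.
#'
#' @param markers a `marker_data` object (or a plain matrix).
#' @param parents a 2 x M character matrix of parental genotypes per marker,
#'   entries like `"AA"`, `"AB"`, `"BB"`.
#' @return the filtered `marker_data` (or matrix), with an attribute
#'   `n_dropped`.
#' @export
filter_informative_markers <- function(markers, parents) {
  W <- if (inherits(markers, "marker_data")) markers$W else markers
  if (ncol(W) != ncol(parents)) stop("parents must have one column per marker")
  het <- parents %in% c("AB", "BA")
  dim(het) <- dim(parents)
  keep <- colSums(het) == 1
  out_W <- W[, keep, drop = FALSE]
  if (inherits(markers, "marker_data")) {
    out <- markers
    out$W <- out_W
    if (!is.null(out$map)) out$map <- out$map[keep, , drop = FALSE]
  } else {
    out <- out_W
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Orthonormal basis of the complement of the intercept (normalized Helmert
# contrasts): an n x (n-1) matrix A with A'A = I and A'1 = 0.
.ortho_contrasts <- function(n) {
  H <- stats::contr.helmert(n)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Fit the RR-BLUP model
#'
#' Fits `Y = mu + X g + e` with `g ~ N(0, I sigma_g2)` and
#' `e ~ N(0, I sigma_e2)` on replicate-level data: each genotype's marker
#' row appears once per phenotypic replicate. The variance ratio
#' `lambda = sigma_e2 / sigma_g2` is estimated by REML through the spectral
#' decomposition of the intercept-projected `X X'`, with a one-dimensional
#' bracketed optimization in log-lambda; `mu` is the generalized
#' least-squares intercept and the marker effects are the BLUP
#' `g = X' (X X' + lambda I)^{-1} (y - mu)`.
#'
#' @param y numeric vector of replicate-level trait values.
#' @param X replicate-level marker matrix (`length(y)` rows).
#' @param K optional precomputed `tcrossprod(X)` (used by cross-validation
#'   to avoid recomputation).
#' @param lambda_interval log-lambda search bracket (default `1e-6 .. 1e6`).
#' @param tol optimization tolerance on log-lambda (default `1e-8`).
#' @return An object of class `gp_fit`: `mu`, `g_hat` (raw effects), `g2`
#'   (rescaled effects; `NULL` until [rescale_effects()]), `sigma_g2`,
#'   `sigma_e2`, `lambda`, `loglik`.
#' @export
rrblup_fit <- function(y, X, K = NULL,
                       lambda_interval = c(1e-6, 1e6), tol = 1e-8) {
  n <- length(y)
  if (nrow(X) != n) stop("X must have one row per phenotype value")
  if (anyNA(y) || anyNA(X)) stop("missing values are not supported")
  if (stats::var(y) == 0) stop("constant y: variance components unidentifiable")
  if (is.null(K)) K <- tcrossprod(X)
  # error contrasts orthogonal to the intercept, then decompose the
  # projected genetic covariance
  A <- .ortho_contrasts(n)
  e <- eigen(crossprod(A, K %*% A), symmetric = TRUE)
  q <- n - 1
  theta <- pmax(e$values, 0)
  if (max(theta) < 1e-10) {
    # no marker variation: pure intercept model
    g0 <- rep(0, ncol(X)); names(g0) <- colnames(X)
    return(structure(list(mu = mean(y), g_hat = g0, g2 = NULL,
                          sigma_g2 = 0, sigma_e2 = stats::var(y),
                          lambda = Inf, loglik = NA_real_),
                     class = "gp_fit"))
  }
  eta <- crossprod(e$vectors, crossprod(A, y))[, 1]
  # profiled restricted log-likelihood in the variance ratio
  rl <- function(loglam) {
    lam <- exp(loglam)
    sg <- sum(eta^2 / (theta + lam)) / q
    -0.5 * (q * log(sg) + sum(log(theta + lam)) + q)
  }
  opt <- stats::optimize(rl, interval = log(lambda_interval),
                         maximum = TRUE, tol = tol)
  lambda <- exp(opt$maximum)
  sigma_g2 <- sum(eta^2 / (theta + lambda)) / q
  sigma_e2 <- lambda * sigma_g2
  Hi <- solve(K + lambda * diag(n))
  one <- rep(1, n)
  mu <- sum(Hi %*% y) / sum(Hi)
  g_hat <- as.numeric(crossprod(X, Hi %*% (y - mu)))
  names(g_hat) <- colnames(X)
  structure(list(mu = mu, g_hat = g_hat, g2 = NULL,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 lambda = lambda, loglik = opt$objective),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> ", length(x$g_hat), " markers, mu = ", signif(x$mu, 4),
      ", sigma_g2 = ", signif(x$sigma_g2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", lambda = ", signif(x$lambda, 4),
      if (!is.null(x$g2)) ", rescaled", "\n", sep = "")
  invisible(x)
}

#' Rescale marker effects to the phenotypic scale
#'
#' BLUP shrinks genetic values toward the mean; to predict on the phenotypic
#' scale, effects are multiplied by the ratio of the standard deviation of
#' the observed phenotypes to that of the genotypic predictions
#' `G = mu + W g_hat`. After rescaling, the standard deviation of
#' `mu + W g2` equals `sd(y)` exactly.
#'
#' @param fit a `gp_fit`.
#' @param y the observed phenotype values (replicate level) whose scale is
#'   targeted.
#' @param W genotype-level marker matrix (one row per genotype).
#' @return the `gp_fit` with `g2` and `sd_ratio` filled.
#' @export
rescale_effects <- function(fit, y, W) {
  G <- as.numeric(fit$mu + W %*% fit$g_hat)
  sd_g <- stats::sd(G)
  if (sd_g == 0) stop("sd of genotypic predictions is zero; cannot rescale")
  ratio <- stats::sd(y) / sd_g
  fit$g2 <- ratio * fit$g_hat
  fit$sd_ratio <- ratio
  fit
}

#' Predict genotype genetic values
#'
#' `G = mu + W g_hat` (raw, shrunken scale).
#'
#' @param fit a `gp_fit`.
#' @param W genotype-level marker matrix.
#' @return numeric vector, one value per row of `W`.
#' @export
predict_genetic_values <- function(fit, W) {
  .check_marker_cols(fit, W, fit$g_hat)
  as.numeric(fit$mu + W %*% fit$g_hat)
}

#' Predict phenotypic-scale parameter values
#'
#' `P = mu + W g2`, using the rescaled effects.
#'
#' @param fit a `gp_fit` that has been through [rescale_effects()].
#' @param W genotype-level marker matrix whose columns match the fit's
#'   marker order.
#' @return numeric vector, one value per row of `W`.
#' @export
predict_phenotypes <- function(fit, W) {
  if (is.null(fit$g2)) stop("fit has no rescaled effects; call rescale_effects() first")
  .check_marker_cols(fit, W, fit$g2)
  as.numeric(fit$mu + W %*% fit$g2)
}

.check_marker_cols <- function(fit, W, g) {
  if (ncol(W) != length(g)) stop("marker column count does not match the fit")
  if (!is.null(colnames(W)) && !is.null(names(g)) &&
      !identical(colnames(W), names(g))) {
    stop("marker column names do not match the fit's marker order")
  }
  invisible(TRUE)
}

#' Cross-validate genomic predictions
#'
#' Genotypes (never single replicates) are assigned to folds, so both
#' replicates of a genotype always travel together. For each fold the model
#' is fitted on the training replicates, effects are rescaled on the
#' training data, and the held-out genotypes' phenotypic-scale predictions
#' are correlated with their observed genotype means. The k-fold accuracy is
#' the mean of the fold-wise correlations (with their SD); leave-one-out
#' accuracy is the single correlation over all genotypes.
#'
#' @param pheno data frame with columns `genotype_id` and `value`
#'   (replicate-level rows).
#' @param W genotype-level marker matrix with `rownames` = genotype ids.
#' @param schema `"kfold"` or `"loo"`.
#' @param k number of folds (k-fold only; default 10). Fold sizes differ by
#'   at most one genotype.
#' @param seed RNG seed for the fold assignment.
#' @return An object of class `cv_report`: list with `schema`, `k`,
#'   `fold_r` (k-fold), `mean`, `sd`, `folds` (assignment), `predicted`,
#'   `observed`, `seed`.
#' @export
cross_validate <- function(pheno, W, schema = c("kfold", "loo"),
                           k = 10L, seed = 1L) {
  schema <- match.arg(schema)
  gids <- rownames(W)
  if (is.null(gids)) stop("W must have genotype ids as rownames")
  if (!all(pheno$genotype_id %in% gids)) {
    stop("phenotype genotypes missing from the marker matrix")
  }
  obs_means <- tapply(pheno$value, factor(pheno$genotype_id, levels = gids), mean)
  K_full <- tcrossprod(W[as.character(pheno$genotype_id), , drop = FALSE])
  fit_predict <- function(train_rows, val_gids) {
    y_tr <- pheno$value[train_rows]
    X_tr <- W[as.character(pheno$genotype_id[train_rows]), , drop = FALSE]
    fit <- rrblup_fit(y_tr, X_tr, K = K_full[train_rows, train_rows])
    fit <- rescale_effects(fit, y_tr,
                           W[unique(as.character(pheno$genotype_id[train_rows])), ,
                             drop = FALSE])
    predict_phenotypes(fit, W[val_gids, , drop = FALSE])
  }
  if (schema == "kfold") {
    n <- length(gids)
    set.seed(seed)
    perm <- sample(gids)
    sizes <- rep(n %/% k, k)
    rem <- n %% k
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    folds <- data.frame(genotype_id = perm, fold = rep(seq_len(k), times = sizes))
    fold_r <- numeric(k)
    pred_all <- stats::setNames(rep(NA_real_, n), gids)
    for (f in seq_len(k)) {
      val <- folds$genotype_id[folds$fold == f]
      if (length(val) < 2) stop("fold ", f, " has fewer than 2 genotypes")
      train_rows <- which(!(pheno$genotype_id %in% val))
      pred <- fit_predict(train_rows, val)
      pred_all[val] <- pred
      fold_r[f] <- stats::cor(pred, obs_means[val])
    }
    structure(list(schema = "kfold", k = k, fold_r = fold_r,
                   mean = mean(fold_r), sd = stats::sd(fold_r),
                   folds = folds, predicted = pred_all,
                   observed = as.numeric(obs_means), seed = seed),
              class = "cv_report")
  } else {
    pred_all <- stats::setNames(rep(NA_real_, length(gids)), gids)
    for (g in gids) {
      train_rows <- which(pheno$genotype_id != g)
      pred_all[g] <- fit_predict(train_rows, g)
    }
    r <- stats::cor(pred_all, as.numeric(obs_means))
    structure(list(schema = "loo", k = NA_integer_, fold_r = NULL,
                   mean = r, sd = NA_real_, folds = NULL,
                   predicted = pred_all, observed = as.numeric(obs_means),
                   seed = seed),
              class = "cv_report")
  }
}

#' @export
print.cv_report <- function(x, ...) {
  if (x$schema == "kfold") {
    cat("<cv_report> 10-fold accuracy: mean r = ", round(x$mean, 3),
        " (sd ", round(x$sd, 3), ") over ", x$k, " folds\n", sep = "")
  } else {
    cat("<cv_report> leave-one-out accuracy: r = ", round(x$mean, 3), "\n",
        sep = "")
  }
  invisible(x)
}
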