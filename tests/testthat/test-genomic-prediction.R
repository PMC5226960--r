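test_that("a zero marker matrix degenerates to the intercept model", {
  set.seed(1)
  y <- rnorm(20, 5)
  X <- matrix(0, 20, 10)
  fit <- rrblup_fit(y, X)
  expect_equal(fit$mu, mean(y))
  expect_true(all(fit$g_hat == 0))
  expect_error(rrblup_fit(rep(1, 20), X), "constant y")
})

test_that("spectral REML agrees with the dense-matrix oracle", {
  d <- small_gp_data(n_geno = 30, n_markers = 51, h2 = 0.8, seed = 7)
  y <- d$pheno$tr
  X <- d$markers$W[as.character(d$pheno$genotype_id), ]
  fit <- rrblup_fit(y, X)
  K <- tcrossprod(X)
  # coarse bracket on a 400-point log grid, then dense-route refinement
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  vals <- vapply(grid, dense_reml_loglik, 0, y = y, K = K)
  j <- which.max(vals)
  ref <- optimize(dense_reml_loglik, y = y, K = K,
                  interval = log(grid[c(max(1, j - 1), min(400, j + 1))]) |>
                    exp(), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(fit$lambda / ref$maximum - 1), 1e-3)
  # effects at the oracle's ratio match the fit's effects
  n <- length(y)
  Hi <- solve(K + ref$maximum * diag(n))
  mu_o <- sum(Hi %*% y) / sum(Hi)
  g_o <- as.numeric(crossprod(X, Hi %*% (y - mu_o)))
  expect_lt(max(abs(fit$g_hat - g_o)) / max(abs(g_o)), 1e-3)
  expect_lt(abs(fit$mu / mu_o - 1), 1e-3)
})

test_that("duplicating every observation leaves the solution direction intact", {
  d <- small_gp_data(n_geno = 25, n_markers = 34, seed = 3)
  y <- d$pheno$tr
  X <- d$markers$W[as.character(d$pheno$genotype_id), ]
  f1 <- rrblup_fit(y, X)
  y2 <- rep(y, 2); X2 <- rbind(X, X)
  f2 <- rrblup_fit(y2, X2)
  # the solver stays on the REML optimum of the duplicated problem
  # (dense-route oracle), and the solution changes only through the
  # variance-ratio re-estimate: intercept stable, effects co-directional
  K2 <- tcrossprod(X2)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 200))
  vals <- vapply(grid, dense_reml_loglik, 0, y = y2, K = K2)
  expect_gte(dense_reml_loglik(f2$lambda, y2, K2), max(vals) - 1e-6)
  expect_equal(f2$mu, f1$mu, tolerance = 0.01)
  expect_gt(cor(f1$g_hat, f2$g_hat), 0.9)
})

test_that("noiseless single-locus data preserves the genotype ranking", {
  set.seed(4)
  W <- matrix(sample(c(-1, 1), 40 * 12, replace = TRUE), 40, 12)
  rownames(W) <- sprintf("G%02d", 1:40)
  g_true <- c(2, rep(0, 11))
  y <- as.numeric(10 + W %*% g_true)
  fit <- rrblup_fit(y, W)
  pred <- predict_genetic_values(fit, W)
  # every strict ordering in the true values is preserved by the
  # predictions (ties in y carry no ordering information)
  ord <- outer(y, y, ">")
  expect_true(all(outer(pred, pred, ">")[ord]))
})

test_that("rescaling pins the predicted dispersion to the observed one", {
  d <- small_gp_data(seed = 11)
  y <- d$pheno$tr
  W <- d$markers$W
  X <- W[as.character(d$pheno$genotype_id), ]
  fit <- rescale_effects(rrblup_fit(y, X), y, W)
  pred <- predict_phenotypes(fit, W)
  expect_equal(sd(pred), sd(y), tolerance = 1e-12)
  # halving the dispersion of y halves the rescaled effects
  y2 <- mean(y) + (y - mean(y)) / 2
  fit2 <- rescale_effects(fit, y2, W)
  expect_equal(fit2$g2, fit$g2 / 2, tolerance = 1e-12)
  # already-matched scales leave effects untouched
  G <- as.numeric(fit$mu + W %*% fit$g_hat)
  fit3 <- rescale_effects(fit, G, W)
  expect_equal(fit3$g2, fit$g_hat, tolerance = 1e-12)
  expect_error(rescale_effects(rrblup_fit(y, X * 0) , y, W * 0), "cannot rescale")
})

test_that("predictions are equivariant to marker column order", {
  d <- small_gp_data(seed = 13)
  y <- d$pheno$tr
  W <- d$markers$W
  X <- W[as.character(d$pheno$genotype_id), ]
  fit <- rescale_effects(rrblup_fit(y, X), y, W)
  perm <- sample(ncol(W))
  fitp <- rescale_effects(rrblup_fit(y, X[, perm]), y, W[, perm])
  expect_equal(predict_phenotypes(fitp, W[, perm]),
               predict_phenotypes(fit, W), tolerance = 1e-8)
  expect_error(predict_phenotypes(fit, W[, perm]), "order")
  expect_error(predict_phenotypes(fit, W[, 1:5]), "column count")
  # zero effects predict the intercept everywhere
  fit0 <- fit; fit0$g2 <- fit$g2 * 0
  expect_equal(predict_phenotypes(fit0, W), rep(fit$mu, nrow(W)))
})

test_that("folds partition genotypes with replicates travelling together", {
  d <- small_gp_data(n_geno = 116, n_markers = 170, seed = 17)
  pheno <- data.frame(genotype_id = d$pheno$genotype_id, value = d$pheno$tr)
  cv <- cross_validate(pheno, d$markers$W, "kfold", k = 10, seed = 2)
  sizes <- table(cv$folds$fold)
  expect_equal(sort(unique(as.vector(sizes))), c(11, 12))
  expect_equal(sum(sizes == 12), 6)  # 116 = 10 x 11 + 6
  expect_setequal(cv$folds$genotype_id, rownames(d$markers$W))
  expect_length(cv$fold_r, 10)
  expect_equal(cv$mean, mean(cv$fold_r))
})

test_that("a pure-noise trait has cross-validated accuracy near zero", {
  d <- small_gp_data(n_geno = 60, n_markers = 85, seed = 19)
  set.seed(19)
  pheno <- data.frame(genotype_id = d$pheno$genotype_id,
                      value = rnorm(nrow(d$pheno)))
  cv <- cross_validate(pheno, d$markers$W, "kfold", k = 10, seed = 4)
  se <- cv$sd / sqrt(cv$k)
  expect_lt(abs(cv$mean), 3 * se)
})

test_that("accuracy ordering: within-sample, leave-one-out, then k-fold", {
  res <- t(sapply(1:10, function(i) {
    d <- small_gp_data(n_geno = 30, n_markers = 68, h2 = 0.8, seed = 100 + i)
    y <- d$pheno$tr
    W <- d$markers$W
    X <- W[as.character(d$pheno$genotype_id), ]
    fit <- rescale_effects(rrblup_fit(y, X), y, W)
    obs <- as.numeric(tapply(y, factor(d$pheno$genotype_id,
                                       levels = rownames(W)), mean))
    pheno <- data.frame(genotype_id = d$pheno$genotype_id, value = y)
    c(within = cor(predict_phenotypes(fit, W), obs),
      loo = cross_validate(pheno, W, "loo")$mean,
      kf = cross_validate(pheno, W, "kfold", k = 10, seed = i)$mean)
  }))
  m <- colMeans(res)
  expect_gt(m["within"], m["loo"])
  expect_gte(m["loo"], m["kf"])
})

test_that("higher heritability yields higher prediction accuracy", {
  accs <- sapply(c(0.2, 0.8), function(h2) {
    mean(sapply(1:5, function(i) {
      d <- small_gp_data(n_geno = 40, n_markers = 68, h2 = h2, seed = 200 + i)
      y <- d$pheno$tr
      W <- d$markers$W
      fit <- rescale_effects(rrblup_fit(y, W[as.character(d$pheno$genotype_id), ]),
                             y, W)
      cor(predict_phenotypes(fit, W), d$truth$genetic_values[, "tr"])
    }))
  })
  expect_gt(accs[2], accs[1])
})

test_that("marker CSVs round-trip and the informative filter drops bad loci", {
  d <- small_gp_data(n_geno = 12, n_markers = 17, seed = 23)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(list(markers = d$markers, truth = d$truth,
                               phenotypes = d$pheno,
                               climates = list(exp1 = simulate_climate(d$config),
                                               exp2 = simulate_climate(d$config, seed = 99)),
                               config = d$config), dir)
  mk <- read_marker_csv(file.path(dir, "markers.csv"), file.path(dir, "map.csv"))
  expect_equal(mk$W, d$markers$W)
  expect_equal(mk$map$marker_id, d$markers$map$marker_id)
  # all generated markers are informative by construction
  kept <- filter_informative_markers(mk, d$markers$parents)
  expect_equal(ncol(kept$W), ncol(mk$W))
  # a marker heterozygous in both parents (or neither) is dropped
  parents2 <- d$markers$parents
  parents2[, 1] <- c("AB", "AB")
  parents2[, 2] <- c("AA", "AA")
  kept2 <- filter_informative_markers(mk, parents2)
  expect_equal(ncol(kept2$W), ncol(mk$W) - 2)
  expect_equal(attr(kept2, "n_dropped"), 2)
})
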