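test_that("transition-region sampling follows w q(1-q) and excludes the states", {
  q <- c(0, 0.5, 0.9, 1, 0.5)
  w <- rep(1, 5)
  idx <- sample_transition_points(q, w, n = 20000, seed = 1)
  expect_false(any(idx %in% c(1, 4)))  # q in {0,1} never sampled
  # two frames with q 0.5 / 0.9: expected ratio 0.25 : 0.09
  q2 <- c(0.5, 0.9)
  idx2 <- sample_transition_points(q2, c(1, 1), n = 50000, seed = 2)
  p_expect <- 0.25 / (0.25 + 0.09)
  p_hat <- mean(idx2 == 1)
  se <- sqrt(p_expect * (1 - p_expect) / 50000)
  expect_lt(abs(p_hat - p_expect), 3 * se)
  # flat probabilities: uniform sampling passes a chi-square test at 1%
  qf <- rep(0.5, 20)
  idxf <- sample_transition_points(qf, rep(1, 20), n = 40000, seed = 3)
  cs <- stats::chisq.test(tabulate(idxf, 20))
  expect_gt(cs$p.value, 0.01)
  expect_error(sample_transition_points(c(0, 1), c(1, 1), 10, 1), "zero")
})

test_that("inverse-sigmoid transforms hit their anchors and invert exactly", {
  expect_equal(transform_committor(0.25, "lower"), 0)
  expect_equal(transform_committor(0.75, "upper"), 0)
  qs <- seq(0.01, 0.49, by = 0.01)
  expect_lt(max(abs(inverse_transform_committor(
    transform_committor(qs, "lower"), "lower") - qs)), 1e-12)
  qs2 <- seq(0.51, 0.99, by = 0.01)
  expect_lt(max(abs(inverse_transform_committor(
    transform_committor(qs2, "upper"), "upper") - qs2)), 1e-12)
  # branches are mirror images: lower(q) = -upper(1-q)
  expect_equal(transform_committor(qs, "lower"),
               -transform_committor(1 - qs, "upper"), tolerance = 1e-12)
  # endpoints are excluded with a count
  out <- transform_committor(c(0, 0.25, 0.5), "lower")
  expect_equal(attr(out, "n_excluded"), 2)
  expect_true(is.na(out[1]) && is.na(out[3]))
})

test_that("lasso: OLS limit, full shrinkage, and the KKT conditions", {
  withr::with_seed(4, {
    X <- matrix(rnorm(600 * 6), 600, 6)
    y <- X %*% c(1, -2, 0, 0, 0.5, 0) + rnorm(600, 0, 0.01)
  })
  colnames(X) <- paste0("f", 1:6)
  m0 <- fit_lasso(X, y, lambda = 0)
  # independent OLS on the same standardized scale
  Xs <- scale(X)
  ols <- stats::coef(stats::lm(y ~ Xs))[-1]
  expect_lt(max(abs(m0$coefficients - ols)), 1e-8)
  expect_gt(m0$r_squared, 0.999)

  mbig <- fit_lasso(X, y, lambda = 1e7)
  expect_true(all(mbig$coefficients == 0))

  # KKT optimality of the coordinate-descent solution
  lam <- 150
  mf <- fit_lasso(X, y, lambda = lam)
  yc <- y - mean(y)
  r <- yc - Xs %*% mf$coefficients
  g <- as.numeric(2 * crossprod(Xs, r))
  active <- abs(mf$coefficients) > 1e-10
  expect_lt(max(abs(g[active] - lam * sign(mf$coefficients[active]))), 1e-6)
  expect_true(all(abs(g[!active]) <= lam + 1e-6))
})

test_that("lasso matches glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  withr::with_seed(5, {
    n <- 500
    X <- matrix(rnorm(n * 8), n, 8)
    y <- X %*% c(2, 0, -1, 0, 0, 0.3, 0, 0) + rnorm(n, 0, 0.2)
  })
  lam <- 120
  mf <- fit_lasso(X, y, lambda = lam)
  Xs <- scale(X)
  g <- glmnet::glmnet(Xs, y, lambda = lam / (2 * n), standardize = FALSE,
                      thresh = 1e-14)
  expect_lt(max(abs(as.numeric(stats::coef(g))[-1] - mf$coefficients)), 1e-6)
})

test_that("lasso path recovers the informative support monotonically", {
  withr::with_seed(6, {
    n <- 2000
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- paste0("f", 1:10)
    y <- 1.5 * X[, 3] - 2 * X[, 7] + rnorm(n, 0, 0.1)
  })
  path <- lasso_path(X, y, lambdas = exp(seq(log(1), log(5000), length.out = 20)))
  sets <- strsplit(path$nonzero, ",")
  # some lambda isolates exactly the informative pair
  expect_true(any(vapply(sets, function(s) setequal(s, c("f3", "f7")), logical(1))))
  # sparsity is monotone along the path (small numerical jitter tolerated)
  n_viol <- sum(diff(path$n_nonzero) < 0)  # lambdas sorted descending
  expect_lte(n_viol, 1)
  # active sets are nested going down the path, up to <= 1 feature of jitter
  for (i in seq_len(length(sets) - 1)) {
    expect_lte(length(setdiff(sets[[i]], sets[[i + 1]])), 1)
  }
})

test_that("lasso drops zero-variance features with a warning", {
  withr::with_seed(7, {
    X <- cbind(rnorm(100), rep(3, 100))
    y <- X[, 1]
  })
  expect_warning(m <- fit_lasso(X, y, 0), "zero-variance")
  expect_length(m$coefficients, 1)
})

test_that("IVAC recovers the relaxation eigenvalue and its lag-window sum", {
  p12 <- 0.1; p21 <- 0.15
  lam2 <- 1 - p12 - p21
  mc <- markov_chain_model(matrix(c(1 - p12, p12, p21, 1 - p21), 2, byrow = TRUE))
  ens <- simulate_chain(mc, 400, 201, seed = 9)
  fl <- flatten_ensemble(ens)
  Xf <- cbind(f1 = as.numeric(fl$values[, 1] == 1), f2 = fl$values[, 1] * 2.5 - 1)
  iv1 <- fit_ivac(Xf, 1, 1, n_dims = 1, traj = fl$traj)
  expect_lt(abs(iv1$eigenvalues[1] - lam2), 0.02)
  ivw <- fit_ivac(Xf, 1, 4, n_dims = 1, traj = fl$traj)
  expect_lt(abs(ivw$eigenvalues[1] - sum(lam2^(1:4))) / sum(lam2^(1:4)), 0.05)
  # constant feature columns are removed as trivial
  ivc <- fit_ivac(cbind(Xf, const = 1), 1, 1, n_dims = 3, traj = fl$traj)
  expect_equal(unname(ivc$kept_columns), 1:2)
  # affine rescaling of inputs changes projections only up to sign/scale
  iv_resc <- fit_ivac(sweep(Xf * 3.7, 2, c(5, -2), "+"), 1, 1, n_dims = 1,
                      traj = fl$traj)
  z1 <- project_ivac(iv1, Xf)[, 1]
  z2 <- project_ivac(iv_resc, sweep(Xf * 3.7, 2, c(5, -2), "+"))[, 1]
  expect_gt(abs(stats::cor(z1, z2)), 1 - 1e-8)
})

test_that("committor monotonicity report behaves under signal, noise, and sign flips", {
  # constructed slow AR(1) coordinate drives a sigmoidal committor
  withr::with_seed(10, {
    z <- as.numeric(stats::arima.sim(list(ar = 0.95), 10000)) / 3
    feats <- cbind(z + rnorm(10000, 0, 0.2), -0.5 * z + rnorm(10000, 0, 0.2),
                   rnorm(10000))
    q <- stats::plogis(2 * z)
  })
  iv <- fit_ivac(feats, 1, 1, n_dims = 2)
  mono <- validate_subspace(iv, feats, q, n_bins = 50)
  expect_gte(abs(mono$spearman_rho), 0.95)
  # random committor: no monotone trend
  q_noise <- withr::with_seed(11, runif(10000))
  mono2 <- validate_subspace(iv, feats, q_noise, n_bins = 50)
  expect_lt(abs(mono2$spearman_rho), 0.3)
  # flipping the projection flips only the sign
  iv_flip <- iv
  iv_flip$projection <- -iv$projection
  mono3 <- validate_subspace(iv_flip, feats, q, n_bins = 50)
  expect_equal(mono3$spearman_rho, -mono$spearman_rho, tolerance = 1e-10)
})
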