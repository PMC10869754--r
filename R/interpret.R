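#' Sample configurations from the transition region
#'
#' Draws `n` frame indices with replacement with probability proportional to
#' `w * q+ * (1 - q+)`, which peaks at the transition state (`q+ = 0.5`) and
#' vanishes on the reactant and product states, so committor models are fit
#' where the committor is informative.
#'
#' @param q_plus per-frame committor in `[0, 1]` (or a `committor_field`).
#' @param weights per-frame equilibrium weights (or a `weight_field`).
#' @param n number of samples (default 100000).
#' @param seed integer seed.
#' @return integer vector of sampled frame indices.
#' @export
sample_transition_points <- function(q_plus, weights, n = 100000, seed = 1L) {
  q <- if (inherits(q_plus, "committor_field")) q_plus$q_plus else as.numeric(q_plus)
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  if (any(q < 0 | q > 1)) stop("q_plus must be clipped to [0, 1] before sampling")
  p <- w * q * (1 - q)
  if (all(p <= 0)) stop("all sampling probabilities are zero")
  withr::with_seed(seed, sample.int(length(p), n, replace = TRUE, prob = p))
}

#' Two-branch inverse-sigmoid committor transforms
#'
#' Maps committor values onto the whole real line so that linear models of
#' the transformed committor predict values in the correct half-range. The
#' lower branch (`q+ < 0.5`, reactant side) uses `ln[2q / (1 - 2q)]` on
#' `(0, 0.5)`; the upper branch uses `ln[(2q - 1) / (2 - 2q)]` on
#' `(0.5, 1)`. Values at the branch endpoints are excluded (`NA`) and their
#' count reported via the `n_excluded` attribute. The branches are mirror
#' images: `lower(q) = -upper(1 - q)` exactly.
#'
#' @param q_plus committor values, pre-clipped to `[0, 1]`.
#' @param branch `"lower"` or `"upper"`.
#' @return transformed values (with attribute `n_excluded`).
#' @export
transform_committor <- function(q_plus, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  q <- as.numeric(q_plus)
  if (any(q < 0 | q > 1)) stop("q_plus must be clipped to [0, 1]")
  out <- if (branch == "lower") {
    ifelse(q > 0 & q < 0.5, log(2 * q / (1 - 2 * q)), NA_real_)
  } else {
    ifelse(q > 0.5 & q < 1, log((2 * q - 1) / (2 - 2 * q)), NA_real_)
  }
  n_exc <- sum(is.na(out))
  if (n_exc > 0) attr(out, "n_excluded") <- n_exc
  out
}

#' @rdname transform_committor
#' @param z transformed values.
#' @export
inverse_transform_committor <- function(z, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  ez <- exp(z)
  if (branch == "lower") ez / (2 * (1 + ez)) else (2 * ez + 1) / (2 * ez + 2)
}

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

# coordinate descent for sum((y - X b)^2) + lambda * sum(|b|),
# run on the Gram matrices so each sweep is O(p^2) regardless of n
lasso_cd <- function(X, y, lambda, tol = 1e-12, maxit = 100000L) {
  p <- ncol(X)
  G <- crossprod(X)          # X'X
  b0 <- as.numeric(crossprod(X, y))  # X'y
  z <- diag(G)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (z[j] == 0) next
      rho <- b0[j] - sum(G[j, ] * beta) + z[j] * beta[j]
      bj <- soft_threshold(rho, lambda / 2) / z[j]
      if (bj != beta[j]) {
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol * max(1, max(abs(beta)))) break
  }
  beta
}

#' L1-penalized sparse committor model
#'
#' Fits `min_beta sum_k (beta' x_k - y_k)^2 + lambda ||beta||_1` on
#' standardized features, where `y` is the inverse-sigmoid-transformed
#' committor of one branch. With `lambda = 0` the fit is the ordinary
#' least-squares solution; large `lambda` shrinks every coefficient to zero.
#' Zero-variance features are dropped with a warning.
#'
#' @param features sampled rows x CVs numeric matrix (raw scale; the fit
#'   standardizes internally and records the transformation).
#' @param y transformed committor values (same rows).
#' @param lambda penalty strength (on the standardized scale).
#' @param branch which committor branch `y` came from (`"lower"`/`"upper"`),
#'   used for back-transformed diagnostics; `NULL` skips them.
#' @return object of class `sparse_committor_model`: `coefficients` (named,
#'   standardized scale), `intercept`, `lambda`, `branch`,
#'   `standardization` (`center`, `scale`), `r_squared` (transformed scale),
#'   `r_squared_backtransformed` (committor scale, if `branch` given),
#'   `nonzero` (names of active features).
#' @export
fit_lasso <- function(features, y, lambda, branch = NULL) {
  X <- as.matrix(features)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(X) < 2) stop("need >= 2 rows with finite transformed committor")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  drop <- scl == 0
  if (any(drop)) warning(sprintf("%d zero-variance feature(s) dropped: %s",
                                 sum(drop), paste(colnames(X)[drop], collapse = ", ")))
  Xs <- sweep(sweep(X[, !drop, drop = FALSE], 2, ctr[!drop]), 2, scl[!drop], "/")
  ybar <- mean(y)
  yc <- y - ybar
  beta <- if (lambda == 0) {
    as.numeric(qr.solve(Xs, yc))  # exact ordinary-least-squares limit
  } else {
    lasso_cd(Xs, yc, lambda)
  }
  names(beta) <- colnames(X)[!drop]
  pred <- as.numeric(Xs %*% beta) + ybar
  tss <- sum(yc^2)
  r2 <- if (tss > 0) 1 - sum((y - pred)^2) / tss else NA_real_
  r2_back <- NA_real_
  if (!is.null(branch)) {
    qhat <- inverse_transform_committor(pred, branch)
    qobs <- inverse_transform_committor(y, branch)
    tssq <- sum((qobs - mean(qobs))^2)
    if (tssq > 0) r2_back <- 1 - sum((qobs - qhat)^2) / tssq
  }
  structure(
    list(coefficients = beta, intercept = ybar, lambda = lambda,
         branch = branch,
         standardization = list(center = ctr[!drop], scale = scl[!drop]),
         r_squared = r2, r_squared_backtransformed = r2_back,
         nonzero = names(beta)[abs(beta) > 1e-10]),
    class = "sparse_committor_model"
  )
}

#' @export
predict.sparse_committor_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coefficients), drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$standardization$center), 2,
              object$standardization$scale, "/")
  as.numeric(Xs %*% object$coefficients) + object$intercept
}

#' @export
print.sparse_committor_model <- function(x, ...) {
  cat(sprintf("sparse_committor_model (%s branch): lambda = %g, %d/%d nonzero, R^2 = %.3f\n",
              if (is.null(x$branch)) "?" else x$branch, x$lambda,
              length(x$nonzero), length(x$coefficients), x$r_squared))
  invisible(x)
}

#' Regularization path of the sparse committor model
#'
#' Fits [fit_lasso()] over a grid of penalties and tabulates the active
#' sets, for choosing a penalty by the sparsity/accuracy tradeoff.
#'
#' @inheritParams fit_lasso
#' @param lambdas numeric vector of penalties (sorted descending
#'   internally).
#' @return data frame with one row per lambda: `lambda`, `n_nonzero`,
#'   `r_squared`, `nonzero` (comma-separated names); fitted models in the
#'   `models` attribute.
#' @export
lasso_path <- function(features, y, lambdas, branch = NULL) {
  lambdas <- sort(lambdas, decreasing = TRUE)
  models <- lapply(lambdas, function(l) fit_lasso(features, y, l, branch))
  out <- data.frame(
    lambda = lambdas,
    n_nonzero = vapply(models, function(m) length(m$nonzero), integer(1)),
    r_squared = vapply(models, function(m) m$r_squared, numeric(1)),
    nonzero = vapply(models, function(m) paste(m$nonzero, collapse = ","),
                     character(1))
  )
  attr(out, "models") <- models
  out
}

#' Lag-integrated variational analysis of conformational dynamics (IVAC)
#'
#' Computes the symmetrized time-lagged covariance integrated over a window
#' of lags, `C_sum = sum_{tau = min_lag}^{max_lag} C(tau)`, and solves the
#' generalized symmetric eigenproblem `C_sum v = lambda C(0) v` after
#' mean-centering the features (which removes the trivial constant mode)
#' and ridging `C(0)` by `ridge`. Eigenvalues are returned in descending
#' order; for a two-state chain with relaxation eigenvalue `lambda_2`, the
#' leading nontrivial eigenvalue equals `sum_tau lambda_2^tau` over the lag
#' window.
#'
#' @param features frames x p matrix (stacked frame order).
#' @param min_lag,max_lag lag window in frames (`1 <= min_lag <= max_lag`).
#' @param n_dims number of nontrivial projections to keep.
#' @param traj optional per-frame trajectory ids (lagged pairs never cross
#'   trajectories); default single trajectory.
#' @param ridge ridge added to `C(0)` (relative to its largest diagonal).
#' @return object of class `ivac_model`: `eigenvalues`, `projection`
#'   (p x n_dims), `center`, `lag_range`, `kept_columns`.
#' @export
fit_ivac <- function(features, min_lag, max_lag, n_dims, traj = NULL,
                     ridge = 1e-10) {
  X <- as.matrix(features)
  stopifnot(min_lag >= 1, max_lag >= min_lag)
  if (is.null(traj)) traj <- rep(1L, nrow(X))
  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  kept <- which(sdv > 0)
  if (length(kept) == 0) stop("all features are constant")
  Xc <- sweep(X[, kept, drop = FALSE], 2, ctr[kept])
  n <- nrow(Xc)
  C0 <- crossprod(Xc) / n
  C0 <- C0 + diag(ridge * max(diag(C0)), ncol(Xc))
  Csum <- matrix(0, ncol(Xc), ncol(Xc))
  for (tau in min_lag:max_lag) {
    ok <- which(diff(traj, lag = tau) == 0)  # start frames with end in same traj
    if (length(ok) == 0) stop(sprintf("no lagged pairs at lag %d", tau))
    Ct <- crossprod(Xc[ok, , drop = FALSE], Xc[ok + tau, , drop = FALSE]) / length(ok)
    Csum <- Csum + (Ct + t(Ct)) / 2
  }
  # generalized symmetric eigenproblem via C0^{-1/2}
  e0 <- eigen(C0, symmetric = TRUE)
  half_inv <- e0$vectors %*% diag(1 / sqrt(pmax(e0$values, 1e-300)),
                                  length(e0$values)) %*% t(e0$vectors)
  es <- eigen(half_inv %*% Csum %*% half_inv, symmetric = TRUE)
  n_dims <- min(n_dims, ncol(Xc))
  proj <- half_inv %*% es$vectors[, seq_len(n_dims), drop = FALSE]
  structure(
    list(eigenvalues = es$values[seq_len(n_dims)], projection = proj,
         center = ctr[kept], kept_columns = kept,
         lag_range = c(min_lag, max_lag), n_dims = n_dims),
    class = "ivac_model"
  )
}

#' Project features onto fitted IVAC coordinates
#'
#' @param model an [fit_ivac()] model.
#' @param features frames x p matrix with the same columns used for the
#'   fit.
#' @return frames x n_dims matrix of IVAC coordinates (tICs).
#' @export
project_ivac <- function(model, features) {
  X <- as.matrix(features)[, model$kept_columns, drop = FALSE]
  sweep(X, 2, model$center) %*% model$projection
}

#' Committor monotonicity along the leading IVAC coordinate
#'
#' Bins frames by the first nontrivial IVAC coordinate and reports the
#' weighted mean committor per bin together with the Spearman rank
#' correlation between bin index and mean committor. A |rho| near 1 says
#' the learned slow coordinate orders configurations by reaction progress.
#'
#' @param model an [fit_ivac()] model.
#' @param features frames x p matrix.
#' @param q_plus per-frame committor (or `committor_field`).
#' @param weights optional per-frame weights (default uniform).
#' @param n_bins number of bins along the coordinate (default 50).
#' @return list with `bin_centers`, `mean_q` (per nonempty bin), `spearman_rho`.
#' @export
validate_subspace <- function(model, features, q_plus, weights = NULL,
                              n_bins = 50) {
  q <- if (inherits(q_plus, "committor_field")) q_plus$q_plus else as.numeric(q_plus)
  w <- if (is.null(weights)) rep(1, length(q))
  else if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  z <- project_ivac(model, features)[, 1]
  br <- seq(min(z), max(z), length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(z, br, rightmost.closed = TRUE), 1L), n_bins)
  num <- tapply(w * q, idx, sum)
  den <- tapply(w, idx, sum)
  bins <- as.integer(names(num))
  mean_q <- as.numeric(num / den)
  rho <- stats::cor(bins, mean_q, method = "spearman")
  list(bin_centers = ((br[-1] + br[-length(br)]) / 2)[bins], mean_q = mean_q,
       spearman_rho = rho)
}
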