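#' Boundary-conforming distance basis for committor estimation
#'
#' Builds the committor basis from per-frame feature vectors and state
#' labels. For each frame, `d_A` and `d_B` are Euclidean distances in
#' z-scored feature space to the nearest `A`- and `B`-labeled frame
#' (distance-to-data; the alternative `mode = "ellipse"` measures distance
#' to the state-ellipse boundary in the (d, theta) plane). From these,
#'
#' * `h = d_A d_B / (d_A + d_B)^2` vanishes on both states,
#' * basis columns `phi_i = x_i h` (standardized feature times `h`) obey the
#'   committor boundary conditions by construction,
#' * the guess `gamma = d_A^2 / (d_A^2 + d_B^2)` is exactly 0 on `A` and 1
#'   on `B`.
#'
#' The columns are whitened by singular value decomposition: the returned
#' basis matrix has orthonormal columns over the dataset, and directions
#' with singular value below `whiten_tol` times the largest are dropped.
#'
#' @param features frames x p numeric matrix.
#' @param labels per-frame labels in `c("A","B","none")`.
#' @param whiten_tol relative singular-value threshold (default `1e-8`).
#' @param mode `"frames"` (nearest labeled frame, default) or `"ellipse"`.
#' @param states state definitions (required for `mode = "ellipse"`).
#' @param cv_table per-frame `(d, theta)` table for `mode = "ellipse"`.
#' @return object of class `basis_set` with elements `values` (whitened
#'   frames x N matrix), `guess`, `h`, `d_A`, `d_B`, `whitening_transform`,
#'   `kind = "distance"`, `n_dropped`.
#' @export
build_distance_basis <- function(features, labels, whiten_tol = 1e-8,
                                 mode = c("frames", "ellipse"),
                                 states = NULL, cv_table = NULL) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  iA <- which(labels == "A")
  iB <- which(labels == "B")
  if (length(iA) == 0 || length(iB) == 0) stop("need at least one frame labeled A and one labeled B")
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) warning(sprintf("%d zero-variance feature(s) dropped", sum(!keep)))
  X <- sweep(sweep(features[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")

  if (mode == "frames") {
    d_A <- nearest_distance(X, X[iA, , drop = FALSE])
    d_B <- nearest_distance(X, X[iB, , drop = FALSE])
    d_A[iA] <- 0
    d_B[iB] <- 0
  } else {
    if (is.null(states) || is.null(cv_table)) stop("mode='ellipse' needs states and cv_table")
    cv_table <- as.matrix(as.data.frame(cv_table))
    vA <- ellipse_value(states$down, cv_table[, "d"], cv_table[, "theta"])
    vB <- ellipse_value(states$up, cv_table[, "d"], cv_table[, "theta"])
    d_A <- pmax(0, sqrt(vA) - 1)
    d_B <- pmax(0, sqrt(vB) - 1)
  }

  denom <- d_A + d_B
  h <- ifelse(denom > 0, d_A * d_B / denom^2, 0)
  denom2 <- d_A^2 + d_B^2
  guess <- ifelse(denom2 > 0, d_A^2 / denom2, 0.5)
  guess[iA] <- 0
  guess[iB] <- 1
  h[c(iA, iB)] <- 0

  phi_raw <- X * h
  sv <- svd(phi_raw)
  keep_sv <- sv$d >= whiten_tol * sv$d[1]
  if (!any(keep_sv)) stop("all basis directions below whitening tolerance")
  W <- sv$v[, keep_sv, drop = FALSE] %*% diag(1 / sv$d[keep_sv], sum(keep_sv))
  values <- phi_raw %*% W
  structure(
    list(values = values, guess = guess, h = h, d_A = d_A, d_B = d_B,
         kind = "distance", whitening_transform = W,
         n_dropped = sum(!keep_sv), feature_center = mu[keep],
         feature_scale = sdv[keep]),
    class = "basis_set"
  )
}

# min Euclidean distance from each row of X to the rows of Y, chunked so the
# cross-product never materializes the full n x m matrix
nearest_distance <- function(X, Y, chunk = 2000L) {
  ny2 <- rowSums(Y^2)
  n <- nrow(X)
  out <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Xi <- X[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), ny2, "+") - 2 * Xi %*% t(Y)
    out[lo:hi] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Clustered indicator basis (Markov state model basis)
#'
#' Reduces the features with lag-integrated variational projection
#' ([fit_ivac()]), clusters the projected frames with k-means, and converts
#' each cluster into an indicator basis function (one-hot rows). With this
#' basis the Galerkin committor estimate is identical to the committor of
#' the empirical cluster-level transition matrix, i.e. a Markov state
#' model.
#'
#' @param ensemble a [short_trajectory_ensemble()], or a plain frames x p
#'   matrix (in which case `traj` ids may be supplied for the IVAC step).
#' @param feature_cols optional column subset used for clustering.
#' @param ivac_dims number of IVAC dimensions to keep before clustering
#'   (0 disables the reduction; default 10, capped at the feature count).
#' @param k number of clusters (default 200, capped at the frame count).
#' @param seed integer seed for k-means (10 restarts, best inertia kept).
#' @param ivac_lags `(min_lag, max_lag)` frames for the IVAC window.
#' @return object of class `basis_set` with `values` (frames x k one-hot
#'   matrix), `assignment` (cluster id per frame), `kind = "indicator"`.
#' @export
build_indicator_basis <- function(ensemble, feature_cols = NULL,
                                  ivac_dims = 10, k = 200, seed = 1L,
                                  ivac_lags = c(1, 5)) {
  if (inherits(ensemble, "short_trajectory_ensemble")) {
    fl <- flatten_ensemble(ensemble)
    X <- fl$values
    traj <- fl$traj
  } else {
    X <- as.matrix(ensemble)
    traj <- rep(1L, nrow(X))
  }
  if (!is.null(feature_cols)) X <- X[, feature_cols, drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of frames")
  ivac_dims <- min(ivac_dims, ncol(X))
  if (ivac_dims > 0 && ncol(X) > 1) {
    iv <- fit_ivac(X, min_lag = ivac_lags[1], max_lag = ivac_lags[2],
                   n_dims = ivac_dims, traj = traj)
    Z <- project_ivac(iv, X)
  } else {
    Z <- X
  }
  km <- NULL
  for (attempt in 0:1) {
    km <- withr::with_seed(seed + attempt, try(
      stats::kmeans(Z, centers = k, nstart = 10, iter.max = 500,
                    algorithm = "MacQueen"),
      silent = TRUE))
    if (!inherits(km, "try-error") && all(km$size > 0)) break
  }
  if (inherits(km, "try-error") || any(km$size == 0)) {
    stop("k-means produced an empty cluster even after re-seeding")
  }
  onehot <- matrix(0, nrow(Z), k)
  onehot[cbind(seq_len(nrow(Z)), km$cluster)] <- 1
  structure(
    list(values = onehot, assignment = km$cluster, centers = km$centers,
         kind = "indicator", guess = NULL, k = k),
    class = "basis_set"
  )
}

#' Impose committor boundary conditions on a basis
#'
#' Zeroes the basis rows of frames labeled `A` or `B` and returns the
#' indicator guess `gamma = 1_B`, so that any linear combination plus the
#' guess satisfies the committor boundary conditions exactly.
#'
#' @param phi frames x N basis matrix.
#' @param labels per-frame labels in `c("A","B","none")`.
#' @return list with `phi` (boundary rows zeroed, all-zero columns dropped)
#'   and `guess`.
#' @export
apply_committor_boundary <- function(phi, labels) {
  phi <- as.matrix(phi)
  boundary <- labels %in% c("A", "B")
  phi[boundary, ] <- 0
  nonzero <- colSums(abs(phi)) > 0
  list(phi = phi[, nonzero, drop = FALSE],
       guess = as.numeric(labels == "B"),
       kept_columns = which(nonzero))
}
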