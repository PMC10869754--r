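#' Assemble short-trajectory correlation matrices
#'
#' Estimates the Galerkin correlation matrices and vectors from stopped
#' (start, end) frame pairs:
#' `C_t[i,j] = mean phi_i(X(0)) phi_j(X(t ^ T))`, `C_0` the same with both
#' factors at the start frame, `r_t[j] = mean phi_j(X(0)) gamma(X(t ^ T))`,
#' `r_0` with the guess at the start frame. These averages over an ensemble
#' of short simulations are all that is needed to solve for committor-like
#' statistics.
#'
#' @param phi frames x N basis matrix (stacked frame order); for committor
#'   systems the rows of state frames must be zero.
#' @param guess per-frame guess function values.
#' @param stopped a [stop_times()] result.
#' @return object of class `correlation_system`: `C_t`, `C_0`, `r_t`, `r_0`,
#'   `lag`, `n_pairs`.
#' @export
assemble_system <- function(phi, guess, stopped) {
  phi <- as.matrix(phi)
  M <- length(stopped$start)
  if (M == 0) stop("no valid start frames")
  if (M <= ncol(phi)) {
    warning(sprintf("only %d transition pairs for %d basis functions", M, ncol(phi)))
  }
  P0 <- phi[stopped$start, , drop = FALSE]
  Pt <- phi[stopped$end, , drop = FALSE]
  structure(
    list(
      C_t = crossprod(P0, Pt) / M,
      C_0 = crossprod(P0, P0) / M,
      r_t = as.numeric(crossprod(P0, guess[stopped$end])) / M,
      r_0 = as.numeric(crossprod(P0, guess[stopped$start])) / M,
      lag = stopped$lag, n_pairs = M
    ),
    class = "correlation_system"
  )
}

# least-squares solve with relative singular-value cutoff
svd_solve <- function(A, b, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d >= rcond * sv$d[1]
  if (!any(keep) || sv$d[1] == 0) {
    stop("singular Galerkin system; increase the whitening tolerance or the lag")
  }
  x <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  list(x = as.numeric(x), cond = sv$d[1] / min(sv$d[keep]),
       n_dropped = sum(!keep))
}

#' Solve the Galerkin committor system
#'
#' Solves `(C_t - C_0) v = -(r_t - r_0)` by least squares with a
#' singular-value cutoff, reconstructs `q+ = gamma + phi v`, clips the
#' values to `[0, 1]` (raw values are kept for diagnostics), and returns the
#' per-frame committor field. Boundary frames are exact by construction
#' (zero basis rows, guess 0 on A and 1 on B).
#'
#' @param system an [assemble_system()] result.
#' @param phi frames x N basis matrix used to build the system.
#' @param guess per-frame guess values.
#' @param rcond relative singular-value cutoff for the solve.
#' @return object of class `committor_field`: `q_plus`, `raw_values`,
#'   `coefficients`, `lag`, `condition_number`.
#' @export
solve_committor <- function(system, phi, guess, rcond = 1e-10) {
  sol <- svd_solve(system$C_t - system$C_0, -(system$r_t - system$r_0), rcond)
  raw <- as.numeric(guess + as.matrix(phi) %*% sol$x)
  structure(
    list(q_plus = pmin(1, pmax(0, raw)), raw_values = raw,
         coefficients = sol$x, lag = system$lag,
         condition_number = sol$cond, n_pairs = system$n_pairs),
    class = "committor_field"
  )
}

#' Solve for equilibrium weights via a cluster-level Markov model
#'
#' Builds the empirical transition matrix among clusters from *unstopped*
#' `(t, t + lag)` pairs, computes its stationary distribution, and assigns
#' each frame the weight `w = pi(cluster) / mu(cluster)` where `mu` is the
#' empirical cluster frequency. Weights are normalized so their frame-mean
#' is 1; weighted averages of observables then estimate equilibrium
#' expectations even though the data were sampled from a non-equilibrium
#' start distribution.
#'
#' If the empirical chain is reducible, the largest closed communicating
#' class is used (with a warning) and frames outside it get weight 0.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @param assignment per-frame cluster ids (e.g. from
#'   [build_indicator_basis()]).
#' @param lag lag in frames.
#' @return object of class `weight_field`: `w` (per frame, mean 1),
#'   `pi_cluster`, `mu_cluster`, `transition_matrix`, `lag`.
#' @export
solve_weights <- function(ensemble, assignment, lag) {
  pairs <- lag_pairs(ensemble, lag)
  k <- max(assignment)
  counts <- table(factor(assignment[pairs$start], levels = seq_len(k)),
                  factor(assignment[pairs$end], levels = seq_len(k)))
  counts <- matrix(as.numeric(counts), k, k)
  active <- which(rowSums(counts) > 0 | colSums(counts) > 0)
  sub <- counts[active, active, drop = FALSE]
  # restrict to the largest closed communicating class
  g <- igraph::graph_from_adjacency_matrix(1 * (sub > 0), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- vapply(seq_len(comp$no), function(cc) {
    members <- which(comp$membership == cc)
    outside <- setdiff(seq_along(active), members)
    length(outside) == 0 || sum(sub[members, outside]) == 0
  }, logical(1))
  sizes <- tabulate(comp$membership, comp$no) * closed
  if (comp$no > 1) {
    best <- which.max(sizes)
    members <- which(comp$membership == best)
    if (length(members) < length(active)) {
      warning(sprintf(
        "empirical cluster chain is reducible; using largest closed class (%d of %d clusters)",
        length(members), length(active)))
    }
    active <- active[members]
    sub <- counts[active, active, drop = FALSE]
  }
  P_hat <- sub / rowSums(sub)
  pi_sub <- exact_stationary(markov_chain_model(P_hat))
  pi_cluster <- numeric(k)
  pi_cluster[active] <- pi_sub
  mu_cluster <- tabulate(assignment, k) / length(assignment)
  w_cluster <- ifelse(mu_cluster > 0, pi_cluster / mu_cluster, 0)
  w <- w_cluster[assignment]
  w <- w / mean(w)
  structure(
    list(w = w, pi_cluster = pi_cluster, mu_cluster = mu_cluster,
         transition_matrix = P_hat, active_clusters = active, lag = lag),
    class = "weight_field"
  )
}

#' Galerkin mean first-passage time to the product state
#'
#' Feynman-Kac analogue of the committor solve with stopping at `B` only:
#' `(C_t - C_0) v = -tau_bar`, where
#' `tau_bar[j] = mean phi_j(X(0)) * elapsed(X, t ^ T_B)` is the average
#' basis-weighted elapsed time to the stopped endpoint. The reconstruction
#' `m = phi v` is floored at 0 and is exactly 0 on `B`.
#'
#' @param phi frames x N basis matrix with zero rows on `B`-labeled frames.
#' @param stopped a [stop_times()] result with `absorbing = "B"`.
#' @param save_interval physical time per frame (default 1, i.e. frame
#'   units).
#' @param rcond relative singular-value cutoff.
#' @return object of class `mfpt_field`: `m` (per frame), `coefficients`,
#'   `lag`, `condition_number`.
#' @export
solve_mfpt <- function(phi, stopped, save_interval = 1, rcond = 1e-10) {
  phi <- as.matrix(phi)
  M <- length(stopped$start)
  P0 <- phi[stopped$start, , drop = FALSE]
  Pt <- phi[stopped$end, , drop = FALSE]
  C_t <- crossprod(P0, Pt) / M
  C_0 <- crossprod(P0, P0) / M
  tau_bar <- as.numeric(crossprod(P0, stopped$elapsed * save_interval)) / M
  sol <- svd_solve(C_t - C_0, -tau_bar, rcond)
  m <- pmax(0, as.numeric(phi %*% sol$x))
  m[stopped$labels == "B"] <- 0
  structure(
    list(m = m, coefficients = sol$x, lag = stopped$lag,
         condition_number = sol$cond, n_pairs = M),
    class = "mfpt_field"
  )
}
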