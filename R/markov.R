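#' Discrete Markov-chain model
#'
#' A finite-state Markov chain defined by a row-stochastic per-lag transition
#' matrix. These chains are the exactly solvable test-bed for the
#' short-trajectory estimators: their committors, stationary distributions,
#' mean first-passage times and reactive currents are all available by direct
#' linear solves (see [exact_committor()], [exact_stationary()],
#' [exact_mfpt()], [exact_tpt()]).
#'
#' @param transition_matrix square numeric matrix; each row must sum to 1
#'   within `1e-12` and all entries must be nonnegative.
#' @param state_labels optional numeric vector or matrix giving collective
#'   variable coordinates per state (one row per state), used when projecting
#'   chain statistics onto CV space.
#' @return an object of class `markov_chain_model` with elements
#'   `n_states`, `transition_matrix`, `state_labels`.
#' @export
markov_chain_model <- function(transition_matrix, state_labels = NULL) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop("transition_matrix must be square")
  if (any(P < 0)) stop("transition_matrix has negative entries")
  rs <- rowSums(P)
  bad <- which(abs(rs - 1) > 1e-12)
  if (length(bad) > 0) {
    stop(sprintf("transition_matrix row %d sums to %.15g, not 1", bad[1], rs[bad[1]]))
  }
  if (!is.null(state_labels)) {
    state_labels <- if (is.matrix(state_labels)) state_labels else matrix(state_labels, ncol = 1)
    if (nrow(state_labels) != nrow(P)) stop("state_labels must have one row per state")
  }
  structure(
    list(n_states = nrow(P), transition_matrix = P, state_labels = state_labels),
    class = "markov_chain_model"
  )
}

#' @export
print.markov_chain_model <- function(x, ...) {
  cat(sprintf("markov_chain_model: %d states\n", x$n_states))
  invisible(x)
}

#' Simulate an ensemble of short Markov-chain trajectories
#'
#' Draws `n_traj` independent trajectories of length `traj_len` frames from
#' the chain, with initial states sampled from `init_dist`. The initial
#' distribution need not be the stationary one; sampling from a spread of
#' start states mimics datasets of short simulations seeded across a
#' transition region.
#'
#' @param model a [markov_chain_model()].
#' @param n_traj number of trajectories.
#' @param traj_len frames per trajectory (>= 2).
#' @param init_dist probability vector over states for the first frame;
#'   defaults to uniform.
#' @param seed integer seed; the ensemble is bit-reproducible given
#'   `(model, n_traj, traj_len, init_dist, seed)`.
#' @param map_labels if `TRUE` and the model carries `state_labels`, frames
#'   are the label coordinates; otherwise frames are integer state indices.
#' @return a [short_trajectory_ensemble()] whose frames are 1-column matrices
#'   of state indices (or label rows).
#' @export
simulate_chain <- function(model, n_traj, traj_len, init_dist = NULL, seed,
                           map_labels = FALSE) {
  stopifnot(inherits(model, "markov_chain_model"), traj_len >= 2, n_traj >= 1)
  S <- model$n_states
  if (is.null(init_dist)) init_dist <- rep(1 / S, S)
  if (length(init_dist) != S) stop("init_dist length must equal n_states")
  if (abs(sum(init_dist) - 1) > 1e-8) stop("init_dist must sum to 1")
  cumP <- t(apply(model$transition_matrix, 1, cumsum))
  states <- matrix(0L, nrow = n_traj, ncol = traj_len)
  withr::with_seed(seed, {
    states[, 1] <- sample.int(S, n_traj, replace = TRUE, prob = init_dist)
    for (t in seq_len(traj_len - 1L)) {
      u <- stats::runif(n_traj)
      cm <- cumP[states[, t], , drop = FALSE]
      # first column whose cumulative probability reaches u
      states[, t + 1L] <- 1L + as.integer(rowSums(cm < u))
    }
  })
  frames <- lapply(seq_len(n_traj), function(m) {
    s <- states[m, ]
    if (map_labels && !is.null(model$state_labels)) {
      model$state_labels[s, , drop = FALSE]
    } else {
      matrix(as.numeric(s), ncol = 1, dimnames = list(NULL, "state"))
    }
  })
  short_trajectory_ensemble(frames, save_interval = 1,
                            start_distribution_tag = "init_dist", seed = seed)
}

check_states <- function(model, A, B = NULL) {
  S <- model$n_states
  if (length(A) == 0) stop("state set A is empty")
  if (!all(A %in% seq_len(S))) stop("A contains invalid state indices")
  if (!is.null(B)) {
    if (length(B) == 0) stop("state set B is empty")
    if (!all(B %in% seq_len(S))) stop("B contains invalid state indices")
    if (length(intersect(A, B)) > 0) stop("A and B must be disjoint")
  }
  invisible(TRUE)
}

#' Exact committor of a Markov chain
#'
#' Solves the committor linear system directly: `q = 0` on `A`, `q = 1` on
#' `B`, and on interior states `q(i) = sum_j P_ij q(j)`. This is the
#' brute-force oracle against which short-trajectory committor estimates are
#' validated.
#'
#' @param model a [markov_chain_model()].
#' @param A,B disjoint nonempty sets of state indices (reactant, product).
#' @return numeric vector of committor probabilities, one per state.
#' @export
exact_committor <- function(model, A, B) {
  check_states(model, A, B)
  P <- model$transition_matrix
  S <- model$n_states
  interior <- setdiff(seq_len(S), union(A, B))
  q <- numeric(S)
  q[B] <- 1
  if (length(interior) > 0) {
    M <- diag(length(interior)) - P[interior, interior, drop = FALSE]
    rhs <- rowSums(P[interior, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stop("singular committor system: some interior states cannot reach A or B")
    })
    q[interior] <- sol
  }
  q
}

#' Exact stationary distribution of an irreducible chain
#'
#' Left Perron eigenvector of the transition matrix, normalized to sum to 1.
#' Computed by a linear solve on `(I - P^T)` with the normalization row
#' appended, which is exact up to round-off for irreducible chains.
#'
#' @inheritParams exact_committor
#' @return probability vector over states, all entries > 0.
#' @export
exact_stationary <- function(model) {
  P <- model$transition_matrix
  S <- model$n_states
  if (!chain_is_irreducible(P)) stop("chain is reducible; stationary distribution not unique")
  # solve pi^T (I - P) = 0 with sum(pi) = 1 via least squares on stacked system
  A <- rbind(t(diag(S) - P), rep(1, S))
  b <- c(numeric(S), 1)
  pi_hat <- as.numeric(qr.solve(A, b))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat / sum(pi_hat)
}

chain_is_irreducible <- function(P) {
  g <- igraph::graph_from_adjacency_matrix(1 * (P > 0), mode = "directed")
  igraph::components(g, mode = "strong")$no == 1
}

#' Exact mean first-passage time to a target set
#'
#' Solves `(I - P) m = 1` on the complement of `B` with `m = 0` on `B`,
#' giving the expected number of lag steps to first reach `B` from every
#' state.
#'
#' @inheritParams exact_committor
#' @param B set of target state indices, reachable from every state.
#' @return numeric vector of expected hitting times (lag-time units).
#' @export
exact_mfpt <- function(model, B) {
  check_states(model, B)
  P <- model$transition_matrix
  S <- model$n_states
  interior <- setdiff(seq_len(S), B)
  m <- numeric(S)
  if (length(interior) > 0) {
    M <- diag(length(interior)) - P[interior, interior, drop = FALSE]
    sol <- tryCatch(solve(M, rep(1, length(interior))), error = function(e) {
      stop("B is not reachable from every state; MFPT system singular")
    })
    if (any(!is.finite(sol)) || any(sol < 0)) {
      stop("B is not reachable from every state; MFPT system ill-posed")
    }
    m[interior] <- sol
  }
  m
}

#' Exact transition-path-theory rate and reactive currents
#'
#' Computes, by direct linear algebra, the stationary distribution, forward
#' and backward committors, per-edge net reactive currents
#' `f_ij = pi_i q-(i) P_ij q+(j) - pi_j q-(j) P_ji q+(i)`, and the reactive
#' rate (total current out of `A`). The per-edge current is divergence-free
#' on interior states, so the net flux through every surface separating `A`
#' from `B` equals the rate.
#'
#' @inheritParams exact_committor
#' @return list with elements `rate`, `current` (S x S antisymmetric matrix
#'   of net edge currents), `q_plus`, `q_minus`, `pi`.
#' @export
exact_tpt <- function(model, A, B) {
  check_states(model, A, B)
  P <- model$transition_matrix
  pi_vec <- exact_stationary(model)
  q_plus <- exact_committor(model, A, B)
  # backward committor of the time-reversed chain: P_rev_ij = pi_j P_ji / pi_i
  P_rev <- t(P * pi_vec) / pi_vec
  P_rev <- P_rev / rowSums(P_rev)
  q_minus <- exact_committor(markov_chain_model(P_rev), B, A)
  gross <- (pi_vec * q_minus) * P * rep(q_plus, each = model$n_states)
  current <- gross - t(gross)
  # net flux out of A (equivalently, by conservation, into B)
  rate <- sum(current[A, , drop = FALSE])
  list(rate = rate, current = current, q_plus = q_plus, q_minus = q_minus,
       pi = pi_vec)
}
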