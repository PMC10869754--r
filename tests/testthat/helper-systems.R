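# Reference systems used across the suite, built in code.

# nearest-neighbour walk on n states with reflecting ends
walk_chain <- function(n, p = 0.5) {
  P <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    P[i, i + 1] <- p
    P[i, i - 1] <- 1 - p
  }
  P[1, 2] <- 1
  P[n, n - 1] <- 1
  markov_chain_model(P)
}

# random banded chain with weak uniform mixing (irreducible, fast-mixing)
rand_chain <- function(n, seed, band = 3, eps = 0.01) {
  withr::with_seed(seed, {
    P <- matrix(eps / n, n, n)
    for (i in 1:n) {
      lo <- max(1, i - band)
      hi <- min(n, i + band)
      P[i, lo:hi] <- P[i, lo:hi] + stats::runif(hi - lo + 1, 0.05, 1)
    }
    markov_chain_model(P / rowSums(P))
  })
}

# reversible two-channel lattice: A at one end, B at the other, a short and
# a long channel in parallel; conductance ratio (Lb+1):(Lt+1)
two_channel_chain <- function(Lt = 3, Lb = 7, h = 0.3, a = 0.25) {
  nS <- 2 + Lt + Lb
  P <- matrix(0, nS, nS)
  top <- 2:(Lt + 1)
  bot <- (Lt + 2):(Lt + Lb + 1)
  fill <- function(P, idx, from, to) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      left <- if (k == 1) from else idx[k - 1]
      right <- if (k == length(idx)) to else idx[k + 1]
      P[i, left] <- h
      P[i, right] <- h
      P[i, i] <- 1 - 2 * h
    }
    P
  }
  P[1, top[1]] <- a; P[1, bot[1]] <- a; P[1, 1] <- 1 - 2 * a
  P <- fill(P, top, 1, nS)
  P <- fill(P, bot, 1, nS)
  P[nS, top[Lt]] <- a; P[nS, bot[Lb]] <- a; P[nS, nS] <- 1 - 2 * a
  span <- Lb + 1
  xy <- rbind(c(0, 0),
              cbind((1:Lt) * span / (Lt + 1), 1),
              cbind((1:Lb) * span / (Lb + 1), -1),
              c(span, 0))
  list(model = markov_chain_model(P), xy = xy, top = top, bot = bot, A = 1, B = nS)
}

onehot_states <- function(state, n) {
  oh <- matrix(0, length(state), n)
  oh[cbind(seq_along(state), state)] <- 1
  oh
}

chain_labels <- function(state, A, B) {
  ifelse(state %in% A, "A", ifelse(state %in% B, "B", "none"))
}

# DGA committor on chain data with the exact indicator basis
dga_chain_committor <- function(ens, state, n_states, A, B, lag = 1) {
  labels <- chain_labels(state, A, B)
  bc <- apply_committor_boundary(onehot_states(state, n_states), labels)
  st <- stop_times(ens, labels, lag)
  cm <- solve_committor(assemble_system(bc$phi, bc$guess, st), bc$phi, bc$guess)
  vapply(seq_len(n_states), function(s) mean(cm$q_plus[state == s]), numeric(1))
}

# simple helix-like structure frame for CV tests
helix_frame <- function(n = 12) {
  t <- seq(0, 4 * pi, length.out = n)
  structure_frame(cbind(cos(t), sin(t), seq(0, 18, length.out = n)),
                  rep("CA", n), seq_len(n))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}

# synthetic frame holding the residues/atoms needed for the 60 committor
# distances (coordinates are arbitrary but reproducible)
synthetic_vsd_frame <- function(seed = 3) {
  resids <- c(217, 223, 226, 229, 232, 129, 136, 151, 164, 183, 186)
  an <- c(); rid <- c()
  for (r in resids) for (a in c("CA", "CZ", "CG", "CD")) {
    an <- c(an, a)
    rid <- c(rid, r)
  }
  coords <- withr::with_seed(seed, matrix(stats::rnorm(length(an) * 3, sd = 5),
                                          ncol = 3))
  structure_frame(coords, an, rid)
}

# the surrogate analysis pipeline is reused by several acceptance checks;
# run it once per session on a small-but-representative problem size
acceptance_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(list(seed = 1), verbose = FALSE)
    }
    cache
  }
})
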