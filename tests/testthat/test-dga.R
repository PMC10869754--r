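test_that("assemble_system matches pencil-and-paper sums on a toy ensemble", {
  # one 6-frame trajectory, 2 basis functions, lag 2, no stopping
  phi <- cbind(c(1, 2, 0, 1, 1, 3), c(0, 1, 1, 0, 2, 1))
  guess <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  ens <- short_trajectory_ensemble(list(matrix(1:6, ncol = 1)))
  st <- stop_times(ens, rep("none", 6), lag = 2)
  sys <- assemble_system(phi, guess, st)
  expect_equal(sys$n_pairs, 4)
  # starts 1..4 pair with ends 3..6
  C_t_hand <- crossprod(phi[1:4, ], phi[3:6, ]) / 4
  C_0_hand <- crossprod(phi[1:4, ], phi[1:4, ]) / 4
  expect_equal(sys$C_t, C_t_hand, tolerance = 1e-14)
  expect_equal(sys$C_0, C_0_hand, tolerance = 1e-14)
  expect_equal(sys$r_t, as.numeric(crossprod(phi[1:4, ], guess[3:6]) / 4),
               tolerance = 1e-14)
  expect_equal(sys$r_0, as.numeric(crossprod(phi[1:4, ], guess[1:4]) / 4),
               tolerance = 1e-14)
  # constant basis column with no stopping: C_t entry is c^2 exactly
  phic <- cbind(rep(2, 6))
  sysc <- assemble_system(phic, guess, st)
  expect_equal(as.numeric(sysc$C_t), 4, tolerance = 1e-14)
  # all starts in A u B annihilate the committor basis
  labsAB <- rep(c("A", "B"), 3)
  stab <- stop_times(ens, labsAB, lag = 2)
  bc <- apply_committor_boundary(phi, labsAB)
  expect_equal(ncol(bc$phi), 0)
})

test_that("DGA committor matches closed forms and the exact oracle", {
  mc5 <- walk_chain(5)
  ens5 <- simulate_chain(mc5, 2500, 41, seed = 11)
  s5 <- as.integer(flatten_ensemble(ens5)$values[, 1])
  q5 <- dga_chain_committor(ens5, s5, 5, A = 1, B = 5)
  expect_lt(max(abs(q5 - (0:4) / 4)), 0.02)

  mc50 <- rand_chain(50, seed = 42)
  qex <- exact_committor(mc50, 1, 50)
  ens50 <- simulate_chain(mc50, 2500, 41, seed = 12)
  s50 <- as.integer(flatten_ensemble(ens50)$values[, 1])
  q50 <- dga_chain_committor(ens50, s50, 50, A = 1, B = 50)
  expect_lte(max(abs(q50 - qex)), 0.05)

  # boundary frames are exact
  labels <- chain_labels(s5, 1, 5)
  bc <- apply_committor_boundary(onehot_states(s5, 5), labels)
  st <- stop_times(ens5, labels, 1)
  cm <- solve_committor(assemble_system(bc$phi, bc$guess, st), bc$phi, bc$guess)
  expect_true(all(cm$q_plus[labels == "B"] == 1))
  expect_true(all(cm$q_plus[labels == "A"] == 0))
})

test_that("committor estimates are stable across lags", {
  mc <- rand_chain(30, seed = 7)
  qex <- exact_committor(mc, 1, 30)
  ens <- simulate_chain(mc, 2500, 41, seed = 14)
  s <- as.integer(flatten_ensemble(ens)$values[, 1])
  qs <- lapply(c(1, 2, 5), function(lg)
    dga_chain_committor(ens, s, 30, A = 1, B = 30, lag = lg))
  for (q in qs) expect_lte(max(abs(q - qex)), 0.05)
  expect_lte(max(abs(qs[[1]] - qs[[3]])), 0.05)
})

test_that("backward committor from time-reversed trajectories is 1 - q+", {
  mc <- walk_chain(8, p = 0.45)  # reversible birth-death chain
  # equilibrium sampling so the reversed trajectories follow the reversed
  # dynamics without reweighting
  ens <- simulate_chain(mc, 2500, 41, init_dist = exact_stationary(mc),
                        seed = 19)
  s <- as.integer(flatten_ensemble(ens)$values[, 1])
  q_fwd <- dga_chain_committor(ens, s, 8, A = 1, B = 8)
  rev_ens <- short_trajectory_ensemble(
    lapply(ens$trajectories, function(tr) tr[rev(seq_len(nrow(tr))), , drop = FALSE]),
    save_interval = ens$save_interval)
  s_rev <- as.integer(flatten_ensemble(rev_ens)$values[, 1])
  q_bwd <- dga_chain_committor(rev_ens, s_rev, 8, A = 8, B = 1)
  expect_lte(max(abs(q_bwd - (1 - q_fwd))), 0.05)
})

test_that("weights are the stationary/sampled ratio and equal 1 at equilibrium", {
  mc <- markov_chain_model(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  piv <- exact_stationary(mc)  # (2/3, 1/3)
  ens <- simulate_chain(mc, 2000, 51, init_dist = piv, seed = 21)
  s <- as.integer(flatten_ensemble(ens)$values[, 1])
  w <- solve_weights(ens, s, lag = 1)
  # equilibrium-sampled data: all weights near 1
  expect_lt(max(abs(w$w - 1)), 0.1)
  # ratio definition holds exactly within the solver output
  ratio <- w$pi_cluster / w$mu_cluster
  expect_equal(unique(round(w$w / (ratio[s] / mean(ratio[s])), 12)), 1)

  # oversampled state 2: mu = (1/2, 1/2) vs pi = (2/3, 1/3) -> w = (4/3, 2/3)
  ens2 <- simulate_chain(mc, 4000, 2, init_dist = c(0.5, 0.5), seed = 22)
  s2 <- as.integer(flatten_ensemble(ens2)$values[, 1])
  w2 <- solve_weights(ens2, s2, lag = 1)
  wc <- vapply(1:2, function(k) mean(w2$w[s2 == k]), numeric(1))
  expect_lt(abs(wc[1] - 4 / 3), 0.1)
  expect_lt(abs(wc[2] - 2 / 3), 0.1)
})

test_that("reweighted expectations on Langevin data match analytic values", {
  kap <- 1.5; kT <- 0.8
  U <- function(x) 0.5 * kap * x[, 1]^2
  g <- function(x) kap * x
  lmod <- langevin_model(U, g, kT = kT, timestep = 0.01, save_interval = 5,
                         dim = 1)
  # deliberately non-equilibrium starts far in one tail
  init <- matrix(withr::with_seed(1, runif(400, 0.5, 2)), ncol = 1)
  ens <- simulate_langevin(lmod, 400, 500, init, seed = 23)
  x <- flatten_ensemble(ens)$values[, 1]
  ib <- build_indicator_basis(ens, ivac_dims = 0, k = 25, seed = 2)
  w <- solve_weights(ens, ib$assignment, lag = 5)
  x2 <- sum(w$w * x^2) / sum(w$w)
  expect_lt(abs(x2 - kT / kap) / (kT / kap), 0.05)
})

test_that("DGA mean first-passage time matches closed form and the oracle", {
  mc11 <- walk_chain(11)
  ens11 <- simulate_chain(mc11, 3000, 41, seed = 13)
  s11 <- as.integer(flatten_ensemble(ens11)$values[, 1])
  lab <- ifelse(s11 == 11, "B", "none")
  phi <- onehot_states(s11, 11)
  phi[lab == "B", ] <- 0
  stB <- stop_times(ens11, lab, lag = 1, absorbing = "B")
  mf <- solve_mfpt(phi, stB)
  m1 <- mean(mf$m[s11 == 1])
  expect_lt(abs(m1 - 100) / 100, 0.1)     # reflecting walk: m(0) = N^2 = 100
  expect_true(all(mf$m[lab == "B"] == 0))
  expect_true(all(mf$m >= 0))

  mc30 <- rand_chain(30, seed = 7)
  em30 <- exact_mfpt(mc30, c(29, 30))
  ens30 <- simulate_chain(mc30, 10000, 41, seed = 14)
  s30 <- as.integer(flatten_ensemble(ens30)$values[, 1])
  lab30 <- ifelse(s30 %in% c(29, 30), "B", "none")
  phi30 <- onehot_states(s30, 30)
  phi30[lab30 == "B", ] <- 0
  st30 <- stop_times(ens30, lab30, lag = 1, absorbing = "B")
  mf30 <- solve_mfpt(phi30, st30)
  mh <- vapply(1:30, function(s) mean(mf30$m[s30 == s]), numeric(1))
  expect_lte(max(abs(mh - em30) / pmax(em30, 1)), 0.1)
})
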