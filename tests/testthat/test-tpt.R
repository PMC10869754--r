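test_that("weighted_pmf: flatness, Boltzmann recovery, normalization invariance", {
  withr::with_seed(1, {
    x <- runif(40000)
  })
  pm <- weighted_pmf(x, rep(1, length(x)), bins = 20, kT = 1)
  # flat distribution: fluctuations stay within a 3-sigma counting bound
  n_per <- length(x) / 20
  bound <- 3 / sqrt(n_per)  # |log(n/nbar)| ~ dn/nbar
  expect_lt(max(pm$free_energy, na.rm = TRUE), 3 * bound)

  # Boltzmann samples from the double well via rejection sampling
  kT <- 0.5
  withr::with_seed(2, {
    xs <- runif(4e5, -1.6, 1.6)
    keep <- runif(4e5) < exp(-((xs^2 - 1)^2) / kT)
    xs <- xs[keep]
  })
  pmb <- weighted_pmf(xs, rep(1, length(xs)), bins = list(seq(-1.6, 1.6, by = 0.1)),
                      kT = kT)
  occ <- !is.na(pmb$free_energy) & pmb$counts > 100
  xc <- pmb$centers[[1]]
  Uc <- (xc^2 - 1)^2
  expect_lt(max(abs((pmb$free_energy - min(pmb$free_energy[occ])) -
                      (Uc - min(Uc[occ])))[occ]), 0.5 * kT)

  # doubling the weights changes nothing
  pm2 <- weighted_pmf(x, rep(2, length(x)), bins = 20, kT = 1)
  expect_equal(pm$free_energy, pm2$free_energy, tolerance = 1e-12)
})

test_that("tilt_pmf adds the linear voltage coupling and is invertible", {
  withr::with_seed(3, q <- c(rnorm(500, -4.2, 0.1), rnorm(500, -3.3, 0.1)))
  pm <- weighted_pmf(q, rep(1, 1000), bins = 30, kT = 0.5961)
  expect_equal(tilt_pmf(pm, 0)$free_energy, pm$free_energy)
  tilted <- tilt_pmf(pm, 50)
  # relative free energy between two charges changes by exactly dQ*V
  occ <- which(!is.na(pm$free_energy))
  i <- occ[1]; j <- occ[length(occ)]
  dQ <- pm$centers[[1]][j] - pm$centers[[1]][i]
  expect_equal((tilted$free_energy[j] - tilted$free_energy[i]) -
                 (pm$free_energy[j] - pm$free_energy[i]),
               dQ * 50 * 0.0230605, tolerance = 1e-12)
  back <- tilt_pmf(tilted, -50)
  expect_equal(back$free_energy, pm$free_energy, tolerance = 1e-12)
})

test_that("conditional averages respect constants and self-consistency", {
  withr::with_seed(4, {
    cv <- cbind(runif(5000), runif(5000))
  })
  w <- rep(1, 5000)
  ca <- conditional_average(rep(2.5, 5000), cv, w, bins = 8)
  expect_true(all(abs(ca$mean[!is.na(ca$mean)] - 2.5) < 1e-12))
  ca2 <- conditional_average(cv[, 1], cv, w, bins = 8)
  centers <- ca2$centers[[1]]
  halfw <- diff(centers[1:2]) / 2
  for (i in seq_along(centers)) {
    row <- ca2$mean[i, ]
    expect_true(all(abs(row[!is.na(row)] - centers[i]) <= halfw + 1e-9))
  }
})

test_that("conditional average of the surrogate charge shows end-basin plateaus", {
  m <- make_vsd_surrogate(seed = 3)
  pts <- withr::with_seed(5, {
    jitter <- cbind(rnorm(4000, 0, 0.35), rnorm(4000, 0, 5))
    base <- m$basin_centers[sample(1:5, 4000, replace = TRUE), ]
    base + jitter
  })
  qd <- m$charge_map(pts)
  ca <- conditional_average(qd, pts, rep(1, 4000), bins = 12)
  # near the two end basins the average charge sits on the plateaus
  i_down <- which.min(abs(ca$centers[[1]] + 4.24))
  j_down <- which.min(abs(ca$centers[[2]] + 56.95))
  i_up <- which.min(abs(ca$centers[[1]] + 0.506))
  j_up <- which.min(abs(ca$centers[[2]] - 3.94))
  expect_lt(abs(ca$mean[i_down, j_down] - (-4.2)), 0.1)
  expect_lt(abs(ca$mean[i_up, j_up] - (-3.2)), 0.1)
})

test_that("committor-binned distributions: self-binning, constants, V-shapes", {
  withr::with_seed(6, q <- runif(20000))
  w <- rep(1, 20000)
  bd <- committor_binned_distributions(q, q, w)
  expect_true(all(abs(bd$median - bd$center) <= 0.05 + 1e-9))
  expect_true(all(bd$q25 <= bd$median & bd$median <= bd$q75))
  bc <- committor_binned_distributions(rep(7, 20000), q, w)
  expect_true(all(bc$q25 == 7 & bc$q75 == 7))
  # non-monotone observable: V-shaped median profile
  obs <- abs(q - 0.37) + withr::with_seed(7, rnorm(20000, 0, 0.02))
  bv <- committor_binned_distributions(obs, q, w)
  imin <- which.min(bv$median)
  expect_gt(imin, 1)
  expect_lt(imin, nrow(bv))
  expect_gt(bv$median[1], bv$median[imin] + 0.1)
  expect_gt(bv$median[nrow(bv)], bv$median[imin] + 0.1)
  # empty bin is masked with count 0
  be <- committor_binned_distributions(q[q < 0.5], q[q < 0.5], w[q < 0.5])
  expect_equal(be$n[be$center == 0.9], 0)
  expect_true(is.na(be$median[be$center == 0.9]))
})

test_that("reactive current vanishes without reactive pairs", {
  # ensemble confined to A: q+ = 0 everywhere
  ens <- short_trajectory_ensemble(list(matrix(rnorm(40), ncol = 2)))
  labels <- rep("A", 20)
  st <- stop_times(ens, labels, 1)
  cf <- reactive_current(flatten_ensemble(ens)$values, rep(0, 20), rep(1, 20),
                         st, bins = 5)
  expect_true(all(cf$current == 0))
})

test_that("1D reactive current is flat in the interior and matches the rate", {
  mc <- walk_chain(9)
  tp <- exact_tpt(mc, 1, 9)
  ens <- simulate_chain(mc, 3000, 41, seed = 21)
  s <- as.integer(flatten_ensemble(ens)$values[, 1])
  labels <- chain_labels(s, 1, 9)
  q <- dga_chain_committor(ens, s, 9, 1, 9)[s]
  w <- solve_weights(ens, s, lag = 1)
  st <- stop_times(ens, labels, 1)
  cf <- reactive_current(matrix(as.numeric(s), ncol = 1), q, w, st,
                         bins = list(seq(0.5, 9.5, by = 1)), lag_time = 1)
  interior <- 3:7
  expect_lt(max(abs(cf$current[interior] - tp$rate)) / tp$rate, 0.15)
})

test_that("two-channel current split matches the exact TPT cut fluxes", {
  tc <- two_channel_chain()
  nS <- nrow(tc$xy)
  tp <- exact_tpt(tc$model, tc$A, tc$B)
  f_top <- tp$current[tc$A, tc$top[1]]
  f_bot <- tp$current[tc$A, tc$bot[1]]
  split_exact <- f_top / (f_top + f_bot)
  ens <- simulate_chain(tc$model, 4000, 41, seed = 31)
  s <- as.integer(flatten_ensemble(ens)$values[, 1])
  labels <- chain_labels(s, tc$A, tc$B)
  q <- exact_committor(tc$model, tc$A, tc$B)[s]
  w <- solve_weights(ens, s, lag = 1)
  st <- stop_times(ens, labels, 1)
  cf <- reactive_current(tc$xy[s, ], q, w, st,
                         bins = list(seq(-0.5, 8.5, by = 1),
                                     seq(-1.5, 1.5, length.out = 8)),
                         lag_time = 1)
  Jx <- cf$current[, , 1]
  interior <- cf$centers[[1]] > 0.5 & cf$centers[[1]] < 7.5
  jt <- sum(Jx[interior, cf$centers[[2]] > 0.3])
  jb <- sum(Jx[interior, cf$centers[[2]] < -0.3])
  expect_lt(abs(jt / (jt + jb) - split_exact) / split_exact, 0.15)
  # flux through a mid cut is within 15% of the rate
  col <- which.min(abs(cf$centers[[1]] - 4))
  expect_lt(abs(sum(Jx[col, ]) - tp$rate) / tp$rate, 0.15)
})

test_that("equilibrium TCF: white noise, two-state closed form, plain-estimator identity", {
  withr::with_seed(8, {
    wn <- lapply(1:50, function(i) matrix(rnorm(200), ncol = 1))
  })
  ens <- short_trajectory_ensemble(wn)
  obs <- flatten_ensemble(ens)$values[, 1]
  tcf <- equilibrium_tcf(obs, rep(1, length(obs)), ens, lags = 1:5)
  expect_true(all(abs(tcf$values) < 3 / sqrt(50 * 195)))

  p <- 0.2
  mc <- markov_chain_model(matrix(c(1 - p, p, p, 1 - p), 2, byrow = TRUE))
  ens2 <- simulate_chain(mc, 500, 101, seed = 9)
  o2 <- ifelse(flatten_ensemble(ens2)$values[, 1] == 1, 1, -1)
  tcf2 <- equilibrium_tcf(o2, rep(1, length(o2)), ens2, lags = 1:8)
  expect_lt(max(abs(tcf2$values - (1 - 2 * p)^(1:8))), 0.03)

  # with w = 1 the estimator IS the plain autocorrelation, bit for bit
  plain <- vapply(1:8, function(tau) {
    pr <- lag_pairs(ens2, tau)
    mean(o2[pr$start] * o2[pr$end])
  }, numeric(1)) / mean(o2^2)
  expect_identical(tcf2$values, plain)
})

test_that("biexponential fits recover generating constants and flag degeneracy", {
  lags <- exp(seq(log(0.005), log(400), length.out = 40))
  vals <- 0.7 * exp(-lags / 59) + 0.3 * exp(-lags / 0.04)
  fit <- fit_biexponential(lags, vals)
  expect_lt(abs(fit$tau1 - 59) / 59, 0.05)
  expect_lt(abs(fit$tau2 - 0.04) / 0.04, 0.05)
  expect_lt(abs(fit$a1 - 0.7), 0.02)
  expect_false(fit$degenerate)

  single <- fit_biexponential(lags, exp(-lags / 5))
  expect_true(single$degenerate ||
                abs(single$tau1 - single$tau2) / single$tau1 < 0.2)
  expect_error(fit_biexponential(lags, rep(1, 40)), "decay")
})

test_that("sensing charge is the difference of state-conditioned charge means", {
  Qd <- c(rep(-4.2, 10), rep(-3.3, 10), rnorm(5))
  labels <- c(rep("A", 10), rep("B", 10), rep("none", 5))
  expect_equal(sensing_charge(Qd, rep(1, 25), labels), 0.9, tolerance = 1e-12)
  # identical state distributions give zero
  expect_equal(sensing_charge(rep(-4, 25), rep(1, 25), labels), 0)
  expect_error(sensing_charge(Qd, rep(1, 25), rep("A", 25)), "populated")
})

test_that("PMF minima detection honors prominence and masks", {
  pm <- list(breaks = list(seq(0, 10, by = 1)), centers = list(seq(0.5, 9.5)),
             free_energy = c(0, 1, 0.9, 1, 2, 0.2, 2, NA, 1, 1.5),
             counts = rep(10, 10), kT = 1)
  class(pm) <- "pmf_grid"
  m_all <- pmf_minima(pm, prominence = 0)
  expect_true(all(c(1, 3, 6) %in% m_all$bin))
  m_prom <- pmf_minima(pm, prominence = 0.5)
  expect_false(3 %in% m_prom$bin)  # shallow dip removed
  expect_true(all(c(1, 6) %in% m_prom$bin))
})
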