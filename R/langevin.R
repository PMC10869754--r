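#' Overdamped Langevin model
#'
#' Continuous-space stochastic dynamics on a model potential-energy surface,
#' integrated with the Euler-Maruyama scheme in the overdamped (high
#' friction) limit:
#' `x <- x - grad(U)(x) * (D/kT) * dt + sqrt(2 D dt) * eta`.
#' Any Markovian surrogate is a valid test system for the short-trajectory
#' estimators, which assume only stochastic Markovian dynamics.
#'
#' @param potential function of an n x dim coordinate matrix returning a
#'   numeric vector of energies (kT-compatible energy units).
#' @param gradient optional analytic gradient, same signature returning an
#'   n x dim matrix; defaults to central finite differences.
#' @param kT thermal energy scale (> 0, or 0 for deterministic descent).
#' @param diffusion diffusion coefficient: scalar or per-dimension vector
#'   (length^2 / time).
#' @param timestep integration time step (> 0).
#' @param save_interval save a frame every this many steps (integer >= 1).
#' @param dim dimensionality of the coordinate space.
#' @return object of class `langevin_model`.
#' @export
langevin_model <- function(potential, gradient = NULL, kT = 1, diffusion = 1,
                           timestep = 1e-3, save_interval = 1L, dim = 1L) {
  stopifnot(timestep > 0, all(diffusion > 0), kT >= 0, save_interval >= 1)
  if (is.null(gradient)) {
    h <- 1e-6
    gradient <- function(x) {
      g <- matrix(0, nrow(x), ncol(x))
      for (j in seq_len(ncol(x))) {
        xp <- x; xm <- x
        xp[, j] <- xp[, j] + h
        xm[, j] <- xm[, j] - h
        g[, j] <- (potential(xp) - potential(xm)) / (2 * h)
      }
      g
    }
  }
  structure(
    list(potential = potential, gradient = gradient, kT = kT,
         diffusion = rep(diffusion, length.out = dim), timestep = timestep,
         save_interval = as.integer(save_interval), dim = as.integer(dim)),
    class = "langevin_model"
  )
}

#' Simulate short overdamped Langevin trajectories
#'
#' Euler-Maruyama integration of all trajectories in parallel (vectorized
#' over the ensemble). Frames are saved every `model$save_interval` steps,
#' starting with the initial points, so `n_steps` integration steps yield
#' `n_steps / save_interval + 1` frames.
#'
#' When `kT = 0` the dynamics are pure gradient descent, so a trajectory
#' started at a local minimum stays there. If the potential changes by more
#' than `kT` over a single deterministic step at the initial points, a
#' warning suggests a smaller timestep.
#'
#' @param model a [langevin_model()].
#' @param n_traj number of trajectories.
#' @param n_steps integration steps per trajectory (multiple of
#'   `save_interval` recommended).
#' @param init_points n_traj x dim matrix of starting coordinates.
#' @param seed integer seed; bit-reproducible given all arguments.
#' @return a [short_trajectory_ensemble()] with `save_interval` equal to
#'   `model$timestep * model$save_interval`.
#' @export
simulate_langevin <- function(model, n_traj, n_steps, init_points, seed) {
  stopifnot(inherits(model, "langevin_model"))
  x <- matrix(as.numeric(init_points), ncol = model$dim)
  if (nrow(x) != n_traj) stop("init_points must supply one row per trajectory")
  dt <- model$timestep
  D <- matrix(model$diffusion, nrow = n_traj, ncol = model$dim, byrow = TRUE)
  mob <- if (model$kT > 0) D / model$kT else D # kT=0: descent with unit-kT mobility
  g0 <- model$gradient(x)
  dU0 <- abs(rowSums(g0 * (-g0 * mob * dt)))
  if (model$kT > 0 && any(dU0 > model$kT)) {
    warning(sprintf(
      "potential changes by up to %.3g (> kT = %.3g) in one step at the initial points; consider a smaller timestep",
      max(dU0), model$kT))
  }
  si <- model$save_interval
  n_frames <- n_steps %/% si + 1L
  frames <- array(0, dim = c(n_traj, model$dim, n_frames))
  frames[, , 1L] <- x
  noise_amp <- sqrt(2 * D * dt) * (model$kT > 0)
  withr::with_seed(seed, {
    for (s in seq_len(n_steps)) {
      g <- model$gradient(x)
      if (any(!is.finite(g))) stop(sprintf("non-finite force at integration step %d", s))
      x <- x - g * mob * dt +
        noise_amp * matrix(stats::rnorm(n_traj * model$dim), n_traj, model$dim)
      if (s %% si == 0L) frames[, , s %/% si + 1L] <- x
    }
  })
  cn <- paste0("x", seq_len(model$dim))
  trajs <- lapply(seq_len(n_traj), function(m) {
    tr <- t(matrix(frames[m, , ], nrow = model$dim))
    colnames(tr) <- cn
    tr
  })
  short_trajectory_ensemble(trajs, save_interval = dt * si,
                            start_distribution_tag = "init_points", seed = seed)
}
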