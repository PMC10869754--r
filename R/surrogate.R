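#' Five-basin voltage-sensor surrogate model
#'
#' A two-dimensional model free-energy landscape emulating the slow
#' collective variables of a voltage-sensing domain: a translocation-like
#' coordinate `d` (length units) and a rotation-like coordinate `theta`
#' (degrees). The potential is a sum of inverted Gaussians placed along a
#' bent piecewise-linear path (rotation advances first, then translocation),
#' confined by a harmonic penalty on the perpendicular distance to the path.
#' The two end basins coincide with the default reactant/product ellipse
#' centers of [default_state_definitions()] and are the deepest, so that
#' equilibrium appears two-state while the interior basins are metastable
#' intermediates.
#'
#' On top of the slow coordinates the model defines:
#' * `feature_map(slow)` — `n_features` deterministic distance-like
#'   observables, loosely coupled to the slow path progress; some are
#'   monotone in progress, some track only one slow coordinate, and at least
#'   one is non-monotone (V-shaped in progress, like an arginine-to-plug
#'   distance that first shrinks and then grows).
#' * `charge_map(slow)` — a charge-like observable with near-discrete
#'   plateaus at the end basins, switching by `charge_gap` (default 1 e)
#'   across the middle of the path.
#'
#' Fast degrees of freedom are emulated at sampling time by adding Gaussian
#' noise of standard deviation `noise_scale` to each feature and
#' `charge_noise` to the charge observable (instantaneous displacement-charge
#' fluctuations in real trajectories are large compared with the spacing of
#' the per-basin means, which is what makes the one-dimensional charge
#' landscape look two-state).
#'
#' @param n_basins number of basins along the path (>= 3; default 5).
#' @param n_features number of distance-like features (>= 10 recommended,
#'   default 20).
#' @param seed integer seed controlling the randomized feature parameters;
#'   `feature_map` is deterministic given the seed.
#' @param depths basin depths in kT; ends must be deepest. Default
#'   `c(7, 5, 5, 5, 7)` (recycled pattern `ends = 7`, `interior = 5` for
#'   other `n_basins`).
#' @param noise_scale per-feature Gaussian noise SD added at sampling time.
#' @param charge_noise per-frame Gaussian noise SD on the charge observable.
#' @param charge_gap charge difference between the end-basin plateaus (e).
#' @return object of class `vsd_surrogate` with elements `potential`,
#'   `gradient`, `basin_centers`, `feature_map`, `charge_map`,
#'   `path_progress`, `noise_scale`, `charge_noise`, `charge_gap`, `kT`.
#' @export
make_vsd_surrogate <- function(n_basins = 5L, n_features = 20L, seed = 1L,
                               depths = NULL, noise_scale = 0.35,
                               charge_noise = 0.15, charge_gap = 1.0) {
  if (n_basins < 3) stop("n_basins must be >= 3")
  if (n_features < 3) stop("n_features must be >= 3")
  # basin centers along a bent path: rotation first, then translocation.
  # Ends match the default down/up state ellipse centers.
  ref <- rbind(
    c(-4.24, -56.95),
    c(-4.10, -36.00),
    c(-3.84, -15.00),
    c(-2.20, -7.00),
    c(-0.506, 3.94)
  )
  centers <- if (n_basins == 5) ref else {
    t_ref <- seq(0, 1, length.out = 5)
    t_new <- seq(0, 1, length.out = n_basins)
    cbind(stats::approx(t_ref, ref[, 1], t_new)$y,
          stats::approx(t_ref, ref[, 2], t_new)$y)
  }
  colnames(centers) <- c("d", "theta")
  if (is.null(depths)) {
    depths <- rep(5, n_basins)
    depths[c(1, n_basins)] <- 7
  }
  if (length(depths) != n_basins) stop("depths must have one entry per basin")
  if (max(depths[-c(1, n_basins)]) >= min(depths[c(1, n_basins)])) {
    stop("end basins must be deepest")
  }
  sig_d <- 0.55
  sig_th <- 7
  th_scale <- 12   # degrees treated as one length unit of path geometry
  k_perp <- 2      # kT per squared scaled unit off the path

  scaled_path <- cbind(centers[, 1], centers[, 2] / th_scale)
  seg <- diff(scaled_path)
  seg_len <- sqrt(rowSums(seg^2))
  cum_len <- c(0, cumsum(seg_len))
  total_len <- cum_len[length(cum_len)]

  # For each scaled point: nearest point on the path, arc-length progress
  project_path <- function(p) {
    n <- nrow(p)
    best_d2 <- rep(Inf, n)
    best_proj <- matrix(0, n, 2)
    best_s <- numeric(n)
    for (k in seq_len(nrow(seg))) {
      a <- scaled_path[k, ]
      v <- seg[k, ]
      tt <- ((p[, 1] - a[1]) * v[1] + (p[, 2] - a[2]) * v[2]) / sum(v^2)
      tt <- pmin(1, pmax(0, tt))
      proj <- cbind(a[1] + tt * v[1], a[2] + tt * v[2])
      d2 <- rowSums((p - proj)^2)
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_proj[upd, ] <- proj[upd, , drop = FALSE]
      best_s[upd] <- (cum_len[k] + tt[upd] * seg_len[k]) / total_len
    }
    list(d2 = best_d2, proj = best_proj, s = best_s)
  }

  slow_mat <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) != 2) stop("slow coordinates must have 2 columns (d, theta)")
    x
  }

  wells <- function(x) {
    x <- slow_mat(x)
    u <- numeric(nrow(x))
    for (k in seq_len(n_basins)) {
      u <- u - depths[k] * exp(-((x[, 1] - centers[k, 1])^2 / (2 * sig_d^2) +
                                   (x[, 2] - centers[k, 2])^2 / (2 * sig_th^2)))
    }
    u
  }

  potential <- function(x) {
    x <- slow_mat(x)
    pr <- project_path(cbind(x[, 1], x[, 2] / th_scale))
    k_perp * pr$d2 + wells(x)
  }

  gradient <- function(x) {
    x <- slow_mat(x)
    g <- matrix(0, nrow(x), 2)
    for (k in seq_len(n_basins)) {
      e <- depths[k] * exp(-((x[, 1] - centers[k, 1])^2 / (2 * sig_d^2) +
                               (x[, 2] - centers[k, 2])^2 / (2 * sig_th^2)))
      g[, 1] <- g[, 1] + e * (x[, 1] - centers[k, 1]) / sig_d^2
      g[, 2] <- g[, 2] + e * (x[, 2] - centers[k, 2]) / sig_th^2
    }
    p <- cbind(x[, 1], x[, 2] / th_scale)
    pr <- project_path(p)
    g[, 1] <- g[, 1] + 2 * k_perp * (p[, 1] - pr$proj[, 1])
    g[, 2] <- g[, 2] + 2 * k_perp * (p[, 2] - pr$proj[, 2]) / th_scale
    g
  }

  path_progress <- function(x) {
    x <- slow_mat(x)
    project_path(cbind(x[, 1], x[, 2] / th_scale))$s
  }

  # randomized feature parameters, fixed by the seed
  par <- withr::with_seed(seed, {
    list(
      scale = stats::runif(n_features, 1.5, 3.5),
      offset = stats::runif(n_features, 4, 10),
      vcenter = stats::runif(n_features, 0.25, 0.75),
      kind = {
        kind <- rep(c("inc", "dec", "vshape", "d_only", "theta_only"),
                    length.out = n_features)
        kind[3] <- "vshape" # guarantee a non-monotone feature
        kind
      }
    )
  })

  feature_map <- function(x) {
    x <- slow_mat(x)
    s <- path_progress(x)
    out <- matrix(0, nrow(x), n_features)
    for (i in seq_len(n_features)) {
      out[, i] <- switch(par$kind[i],
        inc = par$offset[i] + par$scale[i] * s,
        dec = par$offset[i] - par$scale[i] * s,
        vshape = par$offset[i] + par$scale[i] * abs(s - par$vcenter[i]),
        d_only = par$offset[i] + par$scale[i] * (x[, 1] - centers[1, 1]) / 4,
        theta_only = par$offset[i] + par$scale[i] * (x[, 2] - centers[1, 2]) / 60
      )
    }
    colnames(out) <- paste0("dist", seq_len(n_features))
    out
  }

  charge_down <- -4.2
  charge_width <- 0.12
  norm <- stats::plogis(0.5 / charge_width) - stats::plogis(-0.5 / charge_width)
  charge_map <- function(x) {
    s <- path_progress(slow_mat(x))
    charge_down + charge_gap *
      (stats::plogis((s - 0.5) / charge_width) - stats::plogis(-0.5 / charge_width)) / norm
  }

  structure(
    list(potential = potential, gradient = gradient, basin_centers = centers,
         depths = depths, sigma = c(d = sig_d, theta = sig_th),
         feature_map = feature_map, charge_map = charge_map,
         path_progress = path_progress, n_features = n_features,
         noise_scale = noise_scale, charge_noise = charge_noise,
         charge_gap = charge_gap, seed = seed, kT = 1),
    class = "vsd_surrogate"
  )
}

#' @export
print.vsd_surrogate <- function(x, ...) {
  cat(sprintf("vsd_surrogate: %d basins, %d features, charge gap %.2f e\n",
              nrow(x$basin_centers), x$n_features, x$charge_gap))
  invisible(x)
}

#' Count local minima of the surrogate landscape on a grid
#'
#' Enumerates strict local minima (8-neighbour comparison, interior grid
#' points only) of the slow potential on a regular grid. Used to verify the
#' constructed basin count.
#'
#' @param model a [make_vsd_surrogate()] model.
#' @param n grid points per axis (default 200).
#' @param d_range,theta_range axis ranges.
#' @return data frame of minima with columns `d`, `theta`, `energy`.
#' @export
surrogate_grid_minima <- function(model, n = 200,
                                  d_range = c(-5.8, 0.8),
                                  theta_range = c(-80, 20)) {
  d <- seq(d_range[1], d_range[2], length.out = n)
  th <- seq(theta_range[1], theta_range[2], length.out = n)
  gr <- as.matrix(expand.grid(d = d, theta = th))
  U <- matrix(model$potential(gr), n, n)
  mins <- list()
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      v <- U[i, j]
      nb <- U[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v < min(nb[-5])) {
        mins[[length(mins) + 1]] <- c(d[i], th[j], v)
      }
    }
  }
  out <- do.call(rbind, mins)
  out <- as.data.frame(out)
  names(out) <- c("d", "theta", "energy")
  out[order(out$energy), ]
}

#' Sample a short-trajectory ensemble from the surrogate
#'
#' Integrates overdamped Langevin dynamics on the surrogate landscape
#' (kT = 1; diffusion anisotropy chosen so translocation- and rotation-like
#' coordinates relax on comparable timescales relative to their basin
#' widths), starting from a non-equilibrium spread of points placed
#' uniformly along the basin path with small perpendicular jitter — the
#' analogue of seeding short simulations across the transition region. Each
#' saved frame is featurized: columns are the slow CVs `d` and `theta`, the
#' noisy distance-like features, and the noisy charge observable `Qd`.
#'
#' @param model a [make_vsd_surrogate()] model.
#' @param n_traj number of trajectories (default 400).
#' @param n_frames saved frames per trajectory, excluding the start frame
#'   (default 120).
#' @param seed integer seed.
#' @param timestep,save_every integrator step and saving stride.
#' @return a [short_trajectory_ensemble()].
#' @export
sample_surrogate_ensemble <- function(model, n_traj = 400, n_frames = 120,
                                      seed = 1L, timestep = 0.002,
                                      save_every = 25L) {
  stopifnot(inherits(model, "vsd_surrogate"))
  centers <- model$basin_centers
  # uniform-along-path start distribution with jitter
  init <- withr::with_seed(seed + 1L, {
    s <- stats::runif(n_traj)
    nb <- nrow(centers)
    seg <- pmin(floor(s * (nb - 1)) + 1, nb - 1)
    tt <- s * (nb - 1) - (seg - 1)
    pts <- centers[seg, , drop = FALSE] * (1 - tt) +
      centers[seg + 1, , drop = FALSE] * tt
    pts + cbind(stats::rnorm(n_traj, 0, 0.25), stats::rnorm(n_traj, 0, 3))
  })
  lm <- langevin_model(
    potential = model$potential, gradient = model$gradient, kT = model$kT,
    diffusion = c(1, (model$sigma["theta"] / model$sigma["d"])^2),
    timestep = timestep, save_interval = save_every, dim = 2L
  )
  ens <- simulate_langevin(lm, n_traj, n_steps = n_frames * save_every,
                           init_points = init, seed = seed)
  nf <- model$n_features
  trajs <- withr::with_seed(seed + 2L, {
    lapply(ens$trajectories, function(tr) {
      feats <- model$feature_map(tr) +
        matrix(stats::rnorm(nrow(tr) * nf, 0, model$noise_scale), nrow(tr), nf)
      qd <- model$charge_map(tr) + stats::rnorm(nrow(tr), 0, model$charge_noise)
      out <- cbind(tr, feats, Qd = qd)
      colnames(out) <- c("d", "theta", colnames(feats), "Qd")
      out
    })
  })
  short_trajectory_ensemble(trajs, save_interval = ens$save_interval,
                            start_distribution_tag = "uniform_path_jitter",
                            seed = seed)
}
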