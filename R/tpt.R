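#' Weighted potential of mean force
#'
#' Histograms frames on a 1- or 2-dimensional collective-variable grid with
#' equilibrium weights and returns `F(bin) = -kT log(sum of weights)`,
#' shifted so the minimum over occupied bins is 0. Empty bins are `NA`
#' (masked), never 0. Out-of-range frames are dropped and counted.
#'
#' @param cv_values per-frame CV matrix (n x 1 or n x 2) or vector.
#' @param weights per-frame weights (a numeric vector or a `weight_field`).
#' @param bins number of bins per axis (scalar or length-2) or a list of
#'   explicit break vectors.
#' @param kT thermal energy (default 0.5961 kcal/mol, i.e. 300 K).
#' @return object of class `pmf_grid`: `breaks`, `centers`, `free_energy`
#'   (vector or matrix, `NA` when empty), `weight_sum`, `counts`, `kT`,
#'   `n_out_of_range`.
#' @export
weighted_pmf <- function(cv_values, weights, bins = 50, kT = 0.5961) {
  xi <- as.matrix(cv_values)
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  stopifnot(length(w) == nrow(xi))
  nd <- ncol(xi)
  if (!nd %in% c(1, 2)) stop("cv_values must have 1 or 2 columns")
  breaks <- make_breaks(xi, bins)
  idx <- lapply(seq_len(nd), function(j) findInterval(xi[, j], breaks[[j]],
                                                      rightmost.closed = TRUE))
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  ok <- Reduce(`&`, lapply(seq_len(nd), function(j) idx[[j]] >= 1 & idx[[j]] <= nb[j]))
  if (!any(ok)) stop("all frames fall outside the binning range")
  dims <- nb
  flat <- idx[[1]][ok]
  if (nd == 2) flat <- flat + (idx[[2]][ok] - 1L) * nb[1]
  wsum <- numeric(prod(dims))
  cnt <- integer(prod(dims))
  tab_w <- tapply(w[ok], flat, sum)
  tab_n <- tapply(rep(1L, sum(ok)), flat, sum)
  wsum[as.integer(names(tab_w))] <- tab_w
  cnt[as.integer(names(tab_n))] <- tab_n
  Fg <- ifelse(wsum > 0, -kT * log(wsum), NA_real_)
  Fg <- Fg - min(Fg, na.rm = TRUE)
  if (nd == 2) {
    Fg <- matrix(Fg, nb[1], nb[2])
    wsum <- matrix(wsum, nb[1], nb[2])
    cnt <- matrix(cnt, nb[1], nb[2])
  }
  structure(
    list(breaks = breaks,
         centers = lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2),
         free_energy = Fg, weight_sum = wsum, counts = cnt, kT = kT,
         n_out_of_range = sum(!ok)),
    class = "pmf_grid"
  )
}

make_breaks <- function(xi, bins) {
  nd <- ncol(xi)
  if (is.list(bins)) {
    stopifnot(length(bins) == nd)
    return(bins)
  }
  bins <- rep(bins, length.out = nd)
  lapply(seq_len(nd), function(j) {
    r <- range(xi[, j])
    pad <- diff(r) * 1e-8 + 1e-12
    seq(r[1] - pad, r[2] + pad, length.out = bins[j] + 1)
  })
}

#' Tilt a charge PMF by an applied voltage
#'
#' Mimics an applied membrane potential by adding the linear coupling
#' `Q_d * V` to a free-energy profile computed along the displacement
#' charge, then re-shifting the minimum to 0. `V` is in millivolts and the
#' conversion 1 e.mV = 0.0230605 kcal/mol is used, so the PMF must be in
#' kcal/mol along a charge axis in e.
#'
#' @param pmf a one-dimensional [weighted_pmf()] over displacement charge.
#' @param V applied voltage (mV).
#' @param e_mV_per_energy conversion factor (kcal/mol per e.mV).
#' @return a `pmf_grid` with tilted free energies.
#' @export
tilt_pmf <- function(pmf, V, e_mV_per_energy = 0.0230605) {
  stopifnot(inherits(pmf, "pmf_grid"), !is.matrix(pmf$free_energy))
  out <- pmf
  out$free_energy <- pmf$free_energy + pmf$centers[[1]] * V * e_mV_per_energy
  out$free_energy <- out$free_energy - min(out$free_energy, na.rm = TRUE)
  out
}

#' Conditional (bin-wise) weighted average of an observable
#'
#' Weighted mean of an observable on a 1- or 2-dimensional CV grid; empty
#' bins are `NA`.
#'
#' @param observable per-frame values.
#' @param cv_values per-frame CV matrix (n x 1 or n x 2).
#' @param weights per-frame weights or a `weight_field`.
#' @param bins as in [weighted_pmf()].
#' @return list with `breaks`, `centers`, `mean` (vector or matrix),
#'   `counts`.
#' @export
conditional_average <- function(observable, cv_values, weights, bins = 50) {
  xi <- as.matrix(cv_values)
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  stopifnot(length(observable) == nrow(xi), length(w) == nrow(xi))
  breaks <- make_breaks(xi, bins)
  nd <- ncol(xi)
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- lapply(seq_len(nd), function(j) findInterval(xi[, j], breaks[[j]],
                                                      rightmost.closed = TRUE))
  ok <- Reduce(`&`, lapply(seq_len(nd), function(j) idx[[j]] >= 1 & idx[[j]] <= nb[j]))
  flat <- idx[[1]][ok]
  if (nd == 2) flat <- flat + (idx[[2]][ok] - 1L) * nb[1]
  num <- numeric(prod(nb)); den <- numeric(prod(nb)); cnt <- integer(prod(nb))
  tw <- tapply(w[ok] * observable[ok], flat, sum)
  td <- tapply(w[ok], flat, sum)
  tn <- tapply(rep(1L, sum(ok)), flat, sum)
  num[as.integer(names(tw))] <- tw
  den[as.integer(names(td))] <- td
  cnt[as.integer(names(tn))] <- tn
  mu <- ifelse(den > 0, num / den, NA_real_)
  if (nd == 2) {
    mu <- matrix(mu, nb[1], nb[2]); cnt <- matrix(cnt, nb[1], nb[2])
  }
  list(breaks = breaks,
       centers = lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2),
       mean = mu, counts = cnt)
}

# weighted quantiles by linear interpolation of the cumulative weight
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Committor-conditioned distributions of an observable
#'
#' Bins frames by committor value (`|q+ - center| <= halfwidth`) and reports
#' the weighted median and quartiles of the observable in each bin — the
#' numerical content of violin-plot panels of CVs versus committor.
#'
#' @param observable per-frame values.
#' @param q_plus per-frame committor in `[0, 1]` (or a `committor_field`).
#' @param weights per-frame weights or a `weight_field`.
#' @param centers committor bin centers (default 0.1 ... 0.9).
#' @param halfwidth bin half-width (default 0.05).
#' @return data frame with `center`, `n`, `q25`, `median`, `q75` (`NA` rows
#'   for empty bins).
#' @export
committor_binned_distributions <- function(observable, q_plus, weights,
                                           centers = seq(0.1, 0.9, by = 0.1),
                                           halfwidth = 0.05) {
  q <- if (inherits(q_plus, "committor_field")) q_plus$q_plus else as.numeric(q_plus)
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  if (any(q < 0 | q > 1)) stop("q_plus must be clipped to [0, 1]")
  out <- lapply(centers, function(cc) {
    sel <- abs(q - cc) <= halfwidth & w > 0
    if (!any(sel)) {
      return(data.frame(center = cc, n = 0L, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_))
    }
    qs <- weighted_quantile(observable[sel], w[sel], c(0.25, 0.5, 0.75))
    data.frame(center = cc, n = sum(sel), q25 = qs[1], median = qs[2], q75 = qs[3])
  })
  do.call(rbind, out)
}

# separable Gaussian smoothing on a grid; NA-aware (weights renormalized)
gaussian_smooth <- function(x, width) {
  if (width <= 0) return(x)
  r <- max(1L, ceiling(4 * width))
  kern <- stats::dnorm(-r:r, sd = width)
  sm1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      kk <- kern[(lo - i + r + 1):(hi - i + r + 1)]
      vv <- v[lo:hi]
      ok <- !is.na(vv)
      out[i] <- if (any(ok)) sum(kk[ok] * vv[ok]) / sum(kk[ok]) else NA_real_
    }
    out
  }
  if (is.matrix(x)) {
    x <- apply(x, 2, sm1)
    x <- t(apply(x, 1, sm1))
    x
  } else {
    sm1(x)
  }
}

#' Reactive current projected onto collective variables
#'
#' Estimates the flux of reactive (A-to-B) probability on a CV grid from
#' stopped transition pairs. Each pair `(s, e)` deposits the antisymmetrized
#' reactive displacement
#' `w(s) [q-(s) q+(e) - q+(s) q-(e)] (xi(e) - xi(s)) / (2 lag_time)`,
#' split half at the start bin and half at the end bin, normalized as a mean
#' over pairs. The time-reversed contribution enters with opposite sign
#' through the antisymmetrization, so non-reactive recrossings cancel. The
#' field is finally smoothed with a Gaussian kernel of width 1 bin
#' (configurable).
#'
#' @param xi per-frame CV matrix (n x 1 or n x 2).
#' @param q_plus per-frame committor (or `committor_field`).
#' @param weights per-frame weights (or `weight_field`).
#' @param stopped a [stop_times()] result.
#' @param bins as in [weighted_pmf()].
#' @param lag_time physical duration of the lag (default `stopped$lag`
#'   frames, i.e. frame units).
#' @param q_minus backward committor; defaults to `1 - q_plus`
#'   (equilibrium, reversible dynamics).
#' @param smooth_width Gaussian smoothing width in bins (default 1).
#' @return object of class `current_field`: `centers`, `current` (bins x
#'   dims array), `n_deposits`, `smooth_width`.
#' @export
reactive_current <- function(xi, q_plus, weights, stopped, bins = 30,
                             lag_time = NULL, q_minus = NULL,
                             smooth_width = 1) {
  xi <- as.matrix(xi)
  q <- if (inherits(q_plus, "committor_field")) q_plus$q_plus else as.numeric(q_plus)
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  if (is.null(q_minus)) q_minus <- 1 - q
  if (is.null(lag_time)) lag_time <- stopped$lag
  nd <- ncol(xi)
  breaks <- make_breaks(xi, bins)
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  s <- stopped$start; e <- stopped$end
  M <- length(s)
  amp <- w[s] * (q_minus[s] * q[e] - q[s] * q_minus[e]) / (2 * lag_time)
  dxi <- xi[e, , drop = FALSE] - xi[s, , drop = FALSE]
  bin_of <- function(rows) {
    idx <- lapply(seq_len(nd), function(j) {
      b <- findInterval(xi[rows, j], breaks[[j]], rightmost.closed = TRUE)
      pmin(pmax(b, 1L), nb[j])
    })
    flat <- idx[[1]]
    if (nd == 2) flat <- flat + (idx[[2]] - 1L) * nb[1]
    flat
  }
  bs <- bin_of(s); be <- bin_of(e)
  cur <- array(0, dim = c(prod(nb), nd))
  ndep <- numeric(prod(nb))
  for (j in seq_len(nd)) {
    contrib <- amp * dxi[, j] / 2
    t1 <- tapply(contrib, bs, sum)
    t2 <- tapply(contrib, be, sum)
    cur[as.integer(names(t1)), j] <- cur[as.integer(names(t1)), j] + t1
    cur[as.integer(names(t2)), j] <- cur[as.integer(names(t2)), j] + t2
  }
  td <- tapply(rep(1L, M), bs, sum)
  ndep[as.integer(names(td))] <- td
  cur <- cur / M
  if (nd == 2) {
    cur <- array(cur, dim = c(nb[1], nb[2], 2))
    ndep <- matrix(ndep, nb[1], nb[2])
    for (j in 1:2) cur[, , j] <- gaussian_smooth(cur[, , j], smooth_width)
  } else {
    cur <- gaussian_smooth(cur[, 1], smooth_width)
  }
  structure(
    list(centers = lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2),
         breaks = breaks, current = cur, n_deposits = ndep,
         smooth_width = smooth_width, lag_time = lag_time),
    class = "current_field"
  )
}

#' Equilibrium time-correlation function from reweighted short trajectories
#'
#' `C(tau) = sum_t w(t) O(t) O(t + tau) / sum_t w(t)`, computed over all
#' within-trajectory pairs at each requested lag (no stopping applied) and
#' normalized by `C(0)`. With uniform weights on equilibrium data this is
#' the plain autocorrelation estimator.
#'
#' @param observable per-frame values.
#' @param weights per-frame weights (or `weight_field`).
#' @param ensemble a [short_trajectory_ensemble()].
#' @param lags integer vector of lags in frames (0 is added internally for
#'   normalization).
#' @return object of class `tcf_series`: data frame fields `lags` (physical
#'   time), `values` (normalized), plus `C0`.
#' @export
equilibrium_tcf <- function(observable, weights, ensemble, lags) {
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1)) stop("lags must be >= 1")
  nf <- vapply(ensemble$trajectories, nrow, integer(1))
  if (max(lags) >= max(nf)) stop("largest lag exceeds every trajectory")
  C0 <- sum(w * observable^2) / sum(w)
  vals <- vapply(lags, function(tau) {
    pr <- lag_pairs(ensemble, tau)
    sum(w[pr$start] * observable[pr$start] * observable[pr$end]) / sum(w[pr$start])
  }, numeric(1))
  structure(
    list(lags = lags * ensemble$save_interval, values = vals / C0, C0 = C0),
    class = "tcf_series"
  )
}

#' Biexponential fit of a time-correlation function
#'
#' Least-squares fit of `a1 exp(-tau/t1) + a2 exp(-tau/t2)` with
#' `a1 + a2 = 1` and `t1 >= t2 > 0`, using multi-start Levenberg-Marquardt
#' (starting time constants decade-spaced across the lag range). Degenerate
#' fits (`t1` within 20% of `t2`, or a vanishing amplitude) are flagged.
#'
#' @param lags,values the correlation series (e.g. from
#'   [equilibrium_tcf()]); a `tcf_series` may be passed as `lags`.
#' @param n_starts minimum number of multi-start initializations.
#' @return list with `a1`, `tau1`, `a2`, `tau2`, `residual`, `degenerate`.
#' @export
fit_biexponential <- function(lags, values = NULL, n_starts = 5) {
  if (inherits(lags, "tcf_series")) {
    values <- lags$values
    lags <- lags$lags
  }
  stopifnot(length(lags) == length(values), length(lags) >= 8)
  if (stats::sd(values) < 1e-12 || values[which.max(lags)] >= values[which.min(lags)] - 1e-12) {
    stop("correlation series does not decay; biexponential fit is undefined")
  }
  dat <- data.frame(tau = lags, y = values)
  lo <- log(min(lags[lags > 0]) / 10)
  hi <- log(max(lags) * 10)
  t_starts <- exp(seq(lo, hi, length.out = max(4, ceiling(n_starts))))
  best <- NULL
  for (lt1 in t_starts) for (lt2 in t_starts) {
    if (lt2 >= lt1) next
    for (a0 in c(0.3, 0.7)) {
      fit <- try(minpack.lm::nlsLM(
        y ~ a1 * exp(-tau / exp(l1)) + (1 - a1) * exp(-tau / exp(l2)),
        data = dat,
        start = list(a1 = a0, l1 = log(lt1), l2 = log(lt2)),
        lower = c(0, log(min(lags) / 1e3), log(min(lags) / 1e3)),
        upper = c(1, log(max(lags) * 1e3), log(max(lags) * 1e3)),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("biexponential fit failed to converge from all starts")
  p <- stats::coef(best$fit)
  t1 <- exp(p[["l1"]]); t2 <- exp(p[["l2"]]); a1 <- p[["a1"]]
  if (t1 < t2) { tmp <- t1; t1 <- t2; t2 <- tmp; a1 <- 1 - a1 }
  degenerate <- (t1 / t2 < 1.2) || (min(a1, 1 - a1) < 1e-3)
  list(a1 = a1, tau1 = t1, a2 = 1 - a1, tau2 = t2,
       residual = sqrt(best$rss / length(values)), degenerate = degenerate)
}

#' Sensing charge from state-conditioned displacement charges
#'
#' Difference of the weighted mean displacement charge between product
#' (`B`/up) and reactant (`A`/down) labeled frames:
#' `dQ_d = <Q_d>_B - <Q_d>_A`, the gating/sensing charge.
#'
#' @param Qd per-frame displacement charge (e).
#' @param weights per-frame weights (or `weight_field`).
#' @param labels per-frame labels in `c("A","B","none")`.
#' @return sensing charge in e.
#' @export
sensing_charge <- function(Qd, weights, labels) {
  w <- if (inherits(weights, "weight_field")) weights$w else as.numeric(weights)
  iA <- labels == "A"; iB <- labels == "B"
  if (!any(iA) || !any(iB)) stop("both states must be populated")
  sum(w[iB] * Qd[iB]) / sum(w[iB]) - sum(w[iA] * Qd[iA]) / sum(w[iA])
}

#' Local minima of a PMF grid
#'
#' 1D: local minima among occupied bins with a prominence filter (the
#' smallest barrier separating the minimum from any lower region must
#' exceed `prominence`; unoccupied bins act as impassable barriers).
#' 2D: strict local minima over the 8-neighbourhood among occupied bins
#' with free energy at most `max_free_energy`, optionally after Gaussian
#' smoothing (unoccupied bins are filled high before smoothing).
#'
#' @param pmf a [weighted_pmf()] result.
#' @param prominence minimum prominence in energy units (1D; default 0).
#' @param max_free_energy only consider bins at most this far above the
#'   global minimum (default `Inf`).
#' @param smooth_width Gaussian pre-smoothing width in bins (default 0).
#' @return data frame of minima: bin indices, CV centers and free energy.
#' @export
pmf_minima <- function(pmf, prominence = 0, max_free_energy = Inf,
                       smooth_width = 0) {
  Fg <- pmf$free_energy
  if (!is.matrix(Fg)) {
    v <- Fg
    if (smooth_width > 0) v <- gaussian_smooth(v, smooth_width)
    n <- length(v)
    vb <- ifelse(is.na(v), Inf, v)
    mins <- integer(0)
    for (i in seq_len(n)) {
      if (!is.finite(vb[i]) || vb[i] > max_free_energy) next
      left <- if (i > 1) vb[i - 1] else Inf
      right <- if (i < n) vb[i + 1] else Inf
      if (vb[i] < left && vb[i] < right) {
        # prominence: lowest barrier toward any strictly lower bin
        prom_side <- function(idxs) {
          barrier <- -Inf
          for (j in idxs) {
            barrier <- max(barrier, vb[j])
            if (vb[j] < vb[i]) return(barrier - vb[i])
          }
          Inf
        }
        pL <- if (i > 1) prom_side((i - 1):1) else Inf
        pR <- if (i < n) prom_side((i + 1):n) else Inf
        if (min(pL, pR) >= prominence) mins <- c(mins, i)
      }
    }
    data.frame(bin = mins, center = pmf$centers[[1]][mins],
               free_energy = v[mins])
  } else {
    occupied <- !is.na(Fg)
    v <- Fg
    if (smooth_width > 0) {
      fill <- max(Fg, na.rm = TRUE) + 3
      v[!occupied] <- fill
      v <- gaussian_smooth(v, smooth_width)
    }
    v[!occupied] <- NA
    n1 <- nrow(v); n2 <- ncol(v)
    out <- list()
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      if (is.na(v[i, j]) || v[i, j] > max_free_energy) next
      nb <- c()
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        nb <- c(nb, if (ii < 1 || ii > n1 || jj < 1 || jj > n2 || is.na(v[ii, jj]))
          Inf else v[ii, jj])
      }
      if (v[i, j] < min(nb)) {
        out[[length(out) + 1]] <- data.frame(
          bin1 = i, bin2 = j, center1 = pmf$centers[[1]][i],
          center2 = pmf$centers[[2]][j], free_energy = v[i, j])
      }
    }
    if (length(out) == 0) {
      return(data.frame(bin1 = integer(), bin2 = integer(),
                        center1 = numeric(), center2 = numeric(),
                        free_energy = numeric()))
    }
    do.call(rbind, out)
  }
}
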