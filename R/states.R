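#' Metastable state definition
#'
#' A state is an ellipse in the (translocation, rotation) plane,
#' `((d - d0)/rd)^2 + ((theta - theta0)/rtheta)^2 < 1`, optionally
#' intersected with min/max cutoffs on named distance features. Angle
#' differences are wrapped to (-180, 180], so membership is invariant to
#' adding 360 degrees to the rotation.
#'
#' @param center length-2 numeric `(d0, theta0)` (Angstrom, degrees).
#' @param radii length-2 positive numeric `(rd, rtheta)`.
#' @param cutoffs optional named list: each element `list(min=, max=)` for a
#'   feature column name.
#' @return object of class `state_definition`.
#' @export
state_definition <- function(center, radii, cutoffs = NULL) {
  stopifnot(length(center) == 2, length(radii) == 2, all(radii > 0))
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 cutoffs = cutoffs),
            class = "state_definition")
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

ellipse_value <- function(state, d, theta) {
  ((d - state$center[1]) / state$radii[1])^2 +
    (wrap_angle(theta - state$center[2]) / state$radii[2])^2
}

state_member <- function(state, cv_table) {
  inside <- ellipse_value(state, cv_table[, "d"], cv_table[, "theta"]) < 1
  if (!is.null(state$cutoffs)) {
    for (nm in names(state$cutoffs)) {
      if (!nm %in% colnames(cv_table)) stop(sprintf("cutoff feature '%s' not in cv_table", nm))
      co <- state$cutoffs[[nm]]
      if (!is.null(co$min)) inside <- inside & cv_table[, nm] >= co$min
      if (!is.null(co$max)) inside <- inside & cv_table[, nm] <= co$max
    }
  }
  inside
}

#' Default down/up state definitions
#'
#' The reactant (down) and product (up) ellipses in the
#' translocation-rotation plane used for the committor calculations:
#' down centered at (-4.24 A, -56.95 deg) with radii (1.1 A, 8 deg), up
#' centered at (-0.506 A, 3.94 deg) with radii (0.84 A, 7.6 deg). Distance
#' cutoffs default to none ("ellipses only"); they can be supplied per
#' state when available.
#'
#' @return list with elements `down` and `up` ([state_definition()]s).
#' @export
default_state_definitions <- function() {
  list(
    down = state_definition(c(-4.24, -56.95), c(1.1, 8)),
    up = state_definition(c(-0.506, 3.94), c(0.84, 7.6))
  )
}

#' Assign frames to reactant/product states
#'
#' Labels each frame `"A"` (down/reactant), `"B"` (up/product) or `"none"`
#' according to the state ellipses (and any configured distance cutoffs).
#' The two states must be disjoint over the data: a frame matching both is
#' an error.
#'
#' @param cv_table per-frame matrix/data.frame with columns `d` and `theta`
#'   (plus any cutoff feature columns).
#' @param states list with `down` and `up` [state_definition()]s; defaults
#'   to [default_state_definitions()].
#' @return character vector of labels in `c("A", "B", "none")`.
#' @export
assign_states <- function(cv_table, states = default_state_definitions()) {
  cv_table <- as.matrix(as.data.frame(cv_table))
  if (!all(c("d", "theta") %in% colnames(cv_table))) {
    stop("cv_table must have columns 'd' and 'theta'")
  }
  inA <- state_member(states$down, cv_table)
  inB <- state_member(states$up, cv_table)
  if (any(inA & inB)) stop("state definitions overlap: some frames are in both A and B")
  labels <- rep("none", nrow(cv_table))
  labels[inA] <- "A"
  labels[inB] <- "B"
  labels
}

#' Stopped-process bookkeeping
#'
#' For every frame `t` that has a frame `t + lag` within the same
#' trajectory, computes the index of the stopped endpoint
#' `t + (lag ^ first entry into A u B)`: frames already labeled `A` or `B`
#' stop immediately at themselves; otherwise the endpoint is the first
#' later frame (up to `t + lag`) whose label is `A` or `B`, or `t + lag`
#' if none. Also records the elapsed frames to the stopped endpoint.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @param labels per-frame labels (stacked order), values in
#'   `c("A","B","none")`; labels not in `absorbing` are treated as interior.
#' @param lag lag in frames (>= 1, smaller than the longest trajectory).
#' @param absorbing which labels terminate the process (default both
#'   states; use `"B"` for first-passage-time calculations).
#' @return object of class `stopped_ensemble`: list with `start`, `end`
#'   (stacked frame indices of the valid pairs), `elapsed` (frames),
#'   `labels`, `lag`, `n_excluded`.
#' @export
stop_times <- function(ensemble, labels, lag, absorbing = c("A", "B")) {
  fl <- flatten_ensemble(ensemble)
  if (length(labels) != nrow(fl$values)) stop("labels must have one entry per frame")
  pairs <- lag_pairs(ensemble, lag)
  is_abs <- labels %in% absorbing
  # first absorbing frame at or after each stacked index, within trajectory
  n <- length(labels)
  nxt <- rep(NA_integer_, n)
  offsets <- cumsum(c(0L, fl$n_frames))
  for (m in seq_along(fl$n_frames)) {
    lo <- offsets[m] + 1L
    hi <- offsets[m] + fl$n_frames[m]
    nx <- NA_integer_
    for (i in hi:lo) {
      if (is_abs[i]) nx <- i
      nxt[i] <- nx
    }
  }
  end <- pairs$end
  # stopping: frames already absorbing stop at themselves; otherwise first
  # absorbing frame strictly after start, capped at start + lag
  stop_idx <- ifelse(is_abs[pairs$start], pairs$start,
                     pmin(end, ifelse(is.na(nxt[pairs$start + 1L]) |
                                        nxt[pairs$start + 1L] > end,
                                      end, nxt[pairs$start + 1L])))
  structure(
    list(start = pairs$start, end = as.integer(stop_idx),
         elapsed = as.integer(stop_idx - pairs$start), labels = labels,
         lag = as.integer(lag), n_excluded = attr(pairs, "n_excluded")),
    class = "stopped_ensemble"
  )
}
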