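#' Ensemble of short trajectories
#'
#' Container for many fixed-interval trajectories of feature vectors, the
#' data structure at the heart of the short-trajectory estimators. Each
#' trajectory is a frames x features numeric matrix; all trajectories share
#' the feature dimensionality and have at least 2 frames. The sampling
#' distribution of the start points is typically *not* the equilibrium
#' distribution — that is what the weight solver corrects for.
#'
#' @param trajectories list of numeric matrices (frames x features), all with
#'   the same number of columns and >= 2 rows.
#' @param save_interval physical time between consecutive frames.
#' @param start_distribution_tag free-text provenance label for the start
#'   distribution.
#' @param seed integer seed the ensemble was generated with (if any).
#' @return object of class `short_trajectory_ensemble`.
#' @export
short_trajectory_ensemble <- function(trajectories, save_interval = 1,
                                      start_distribution_tag = "unknown",
                                      seed = NA_integer_) {
  if (!is.list(trajectories) || length(trajectories) == 0) {
    stop("trajectories must be a nonempty list of matrices")
  }
  trajectories <- lapply(trajectories, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  p <- ncol(trajectories[[1]])
  for (i in seq_along(trajectories)) {
    if (ncol(trajectories[[i]]) != p) stop("all trajectories must share feature dimensionality")
    if (nrow(trajectories[[i]]) < 2) stop("each trajectory needs >= 2 frames")
  }
  if (save_interval <= 0) stop("save_interval must be positive")
  structure(
    list(trajectories = trajectories, save_interval = save_interval,
         start_distribution_tag = start_distribution_tag, seed = seed),
    class = "short_trajectory_ensemble"
  )
}

#' @export
print.short_trajectory_ensemble <- function(x, ...) {
  n <- length(x$trajectories)
  nf <- vapply(x$trajectories, nrow, integer(1))
  cat(sprintf(
    "short_trajectory_ensemble: %d trajectories, %d frames total, %d features, save_interval %g\n",
    n, sum(nf), ncol(x$trajectories[[1]]), x$save_interval))
  invisible(x)
}

#' Flatten an ensemble into a stacked frame table
#'
#' Stacks all trajectories into one frames x features matrix plus per-frame
#' trajectory ids and within-trajectory frame indices (0-based). All
#' per-frame fields in the package (labels, committors, weights) are aligned
#' with this stacked order.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @return list with `values` (matrix), `traj` (integer), `frame` (integer,
#'   0-based), `n_frames` per trajectory.
#' @export
flatten_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "short_trajectory_ensemble"))
  nf <- vapply(ensemble$trajectories, nrow, integer(1))
  list(
    values = do.call(rbind, ensemble$trajectories),
    traj = rep(seq_along(nf), nf),
    frame = unlist(lapply(nf, function(n) seq_len(n) - 1L), use.names = FALSE),
    n_frames = nf
  )
}

#' Indices of valid (start, start+lag) frame pairs
#'
#' Returns stacked-frame row indices of all frames `t` such that `t + lag`
#' lies in the same trajectory, together with the row index of `t + lag`.
#' Trajectories shorter than `lag + 1` contribute no pairs; their count is
#' reported via the `n_excluded` attribute.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @param lag lag in frames (>= 1).
#' @return list with integer vectors `start`, `end` (stacked row indices).
#' @export
lag_pairs <- function(ensemble, lag) {
  stopifnot(lag >= 1)
  nf <- vapply(ensemble$trajectories, nrow, integer(1))
  if (all(nf <= lag)) stop("lag is >= every trajectory length; no valid pairs")
  offsets <- cumsum(c(0L, nf[-length(nf)]))
  starts <- unlist(lapply(seq_along(nf), function(m) {
    if (nf[m] > lag) offsets[m] + seq_len(nf[m] - lag) else integer(0)
  }), use.names = FALSE)
  out <- list(start = starts, end = starts + as.integer(lag))
  attr(out, "n_excluded") <- sum(nf <= lag)
  out
}

#' Write / read an ensemble as a flat CSV table
#'
#' One row per frame with `traj_id` and `frame_id` (0-based) columns followed
#' by the feature columns; `save_interval` and `seed` are stored in a
#' `# key: value` comment header.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  fl <- flatten_ensemble(ensemble)
  vals <- fl$values
  if (is.null(colnames(vals))) colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  df <- data.frame(traj_id = fl$traj, frame_id = fl$frame, vals,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# save_interval: %.17g", ensemble$save_interval), con)
  writeLines(sprintf("# seed: %s", ensemble$seed), con)
  writeLines(sprintf("# start_distribution_tag: %s", ensemble$start_distribution_tag), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list(save_interval = 1, seed = NA, start_distribution_tag = "unknown")
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  feat_cols <- setdiff(colnames(df), c("traj_id", "frame_id"))
  trajs <- lapply(split(df[feat_cols], df$traj_id), function(d) as.matrix(d))
  names(trajs) <- NULL
  short_trajectory_ensemble(
    trajs,
    save_interval = as.numeric(meta$save_interval),
    start_distribution_tag = as.character(meta$start_distribution_tag),
    seed = suppressWarnings(as.integer(meta$seed))
  )
}

#' Map a per-frame function over an ensemble
#'
#' Applies `f` to the stacked frame matrix and returns a per-frame vector or
#' matrix aligned with [flatten_ensemble()] order.
#'
#' @param ensemble a [short_trajectory_ensemble()].
#' @param f function taking a frames x features matrix.
#' @return whatever `f` returns on the stacked matrix.
#' @export
ensemble_apply <- function(ensemble, f) {
  f(flatten_ensemble(ensemble)$values)
}
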