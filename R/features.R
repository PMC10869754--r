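#' Structure frame
#'
#' Minimal container for a single molecular configuration: coordinates in
#' Angstrom with atom/residue identifiers, and optionally per-atom partial
#' charges, unwrapped z-coordinates and the box length along z (required for
#' the displacement charge).
#'
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param atom_name character vector of atom names (e.g. `"CA"`, `"CZ"`).
#' @param resid integer residue ids.
#' @param resname optional residue names.
#' @param charge optional per-atom partial charges (e).
#' @param mass optional per-atom masses; defaults inferred from the element
#'   implied by the atom name.
#' @param box_length_z optional box length along z (Angstrom).
#' @param unwrapped_z optional per-atom unwrapped z-coordinates (Angstrom).
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(coords, atom_name, resid, resname = NULL,
                            charge = NULL, mass = NULL, box_length_z = NULL,
                            unwrapped_z = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix")
  if (any(!is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  stopifnot(length(atom_name) == n, length(resid) == n)
  if (!is.null(box_length_z) && box_length_z <= 0) stop("box_length_z must be positive")
  if (is.null(mass)) mass <- infer_mass(atom_name)
  structure(
    list(coords = coords, atom_name = as.character(atom_name),
         resid = as.integer(resid), resname = resname, charge = charge,
         mass = mass, box_length_z = box_length_z, unwrapped_z = unwrapped_z),
    class = "structure_frame"
  )
}

# standard atomic masses from the element implied by the atom name
infer_mass <- function(atom_name) {
  elem <- toupper(substr(gsub("^[0-9]+", "", atom_name), 1, 1))
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974, F = 18.998)
  m <- masses[elem]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Select atom indices by residue id and atom name
#'
#' The minimal selection language used throughout: a set of residue ids
#' and/or atom names; `NULL` means no restriction on that field.
#'
#' @param frame a [structure_frame()].
#' @param resid,atom_name,resname optional filters.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(frame, resid = NULL, atom_name = NULL, resname = NULL) {
  keep <- rep(TRUE, nrow(frame$coords))
  if (!is.null(resid)) keep <- keep & frame$resid %in% resid
  if (!is.null(atom_name)) keep <- keep & frame$atom_name %in% atom_name
  if (!is.null(resname) && !is.null(frame$resname)) keep <- keep & frame$resname %in% resname
  which(keep)
}

com <- function(frame, idx) {
  w <- frame$mass[idx]
  colSums(frame$coords[idx, , drop = FALSE] * w) / sum(w)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotates and translates `mobile` so that the RMSD of the selected atoms to
#' `reference` is the global minimum over all proper rigid transforms. The
#' rotation is computed from the SVD of the covariance of the centered
#' selections, with the determinant corrected to +1 (no reflections).
#'
#' @param mobile,reference [structure_frame()]s with matching selections.
#' @param selection atom indices (>= 3 non-collinear atoms) present in both.
#' @return list with `frame` (aligned mobile), `rotation` (3 x 3, applied to
#'   row vectors on the right), `rmsd` over the selection.
#' @export
kabsch_align <- function(mobile, reference, selection) {
  if (length(selection) < 3) stop("selection needs >= 3 atoms")
  A <- mobile$coords[selection, , drop = FALSE]
  B <- reference$coords[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2 || qr(Bc)$rank < 2) stop("selection is collinear/degenerate")
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  new_coords <- sweep(sweep(mobile$coords, 2, ca) %*% R, 2, cb, "+")
  out <- mobile
  out$coords <- new_coords
  rmsd <- sqrt(mean(rowSums((new_coords[selection, , drop = FALSE] - B)^2)))
  list(frame = out, rotation = R, rmsd = rmsd)
}

principal_axis <- function(frame, idx) {
  x <- frame$coords[idx, , drop = FALSE]
  w <- frame$mass[idx]
  cm <- colSums(x * w) / sum(w)
  xc <- sweep(x, 2, cm)
  # direction of greatest mass-weighted extent = smallest moment of inertia
  C <- crossprod(xc * sqrt(w / sum(w)))
  ax <- eigen(C, symmetric = TRUE)$vectors[, 1]
  # orient toward +z (fall back to first nonzero component)
  s <- if (abs(ax[3]) > 1e-12) sign(ax[3]) else sign(ax[which(abs(ax) > 1e-12)[1]])
  ax * s
}

#' Translocation along an axis (distanceZ-style collective variable)
#'
#' Projection of the displacement between the centers of mass of a selection
#' in `frame` and in `reference` onto an axis. The frame is assumed to be
#' pre-aligned on a static selection (e.g. the S1-S3 helices). The default
#' axis is the principal inertial axis of the reference selection, oriented
#' toward +z.
#'
#' @param frame,reference [structure_frame()]s.
#' @param selection atom indices of the mobile group (e.g. S4 C-alpha atoms).
#' @param axis optional unit 3-vector.
#' @return signed distance in Angstrom.
#' @export
distance_z <- function(frame, reference, selection, axis = NULL) {
  if (length(selection) == 0) stop("empty selection")
  if (is.null(axis)) axis <- principal_axis(reference, selection)
  axis <- axis / sqrt(sum(axis^2))
  sum((com(frame, selection) - com(reference, selection)) * axis)
}

#' Rotation about an axis (spinAngle-style collective variable)
#'
#' The angle of rotation about the axis through the selection's center of
#' mass that best superposes the reference selection onto the frame
#' selection, computed in closed form from axis-perpendicular components:
#' `theta = atan2(sum m (a_perp x b_perp) . e, sum m a_perp . b_perp)`.
#' Positive angles are right-handed rotations about the axis (oriented
#' toward the extracellular side, i.e. +z, by default), so a frame equal to
#' the reference rotated by -60 degrees reports -60.
#'
#' @inheritParams distance_z
#' @return angle in degrees in (-180, 180].
#' @export
spin_angle <- function(frame, reference, selection, axis = NULL) {
  if (length(selection) == 0) stop("empty selection")
  if (is.null(axis)) axis <- principal_axis(reference, selection)
  e <- axis / sqrt(sum(axis^2))
  w <- reference$mass[selection]
  a <- sweep(reference$coords[selection, , drop = FALSE], 2, com(reference, selection))
  b <- sweep(frame$coords[selection, , drop = FALSE], 2, com(frame, selection))
  perp <- function(x) x - outer(drop(x %*% e), e)
  ap <- perp(a); bp <- perp(b)
  if (all(sqrt(rowSums(ap^2)) < 1e-9)) stop("all atoms lie on the axis; angle undefined")
  crossmat <- cbind(ap[, 2] * bp[, 3] - ap[, 3] * bp[, 2],
                    ap[, 3] * bp[, 1] - ap[, 1] * bp[, 3],
                    ap[, 1] * bp[, 2] - ap[, 2] * bp[, 1])
  s <- sum(w * drop(crossmat %*% e))
  c <- sum(w * rowSums(ap * bp))
  theta <- atan2(s, c) * 180 / pi
  if (theta <= -180) theta <- theta + 360
  theta
}

#' Displacement charge (Q-route)
#'
#' `Q_d = sum_i q_i (z_i^(u) + Lz/2) / Lz` over all atoms, using *unwrapped*
#' z-coordinates (periodic images must not be folded back) and the box
#' length along z. Silently substituting wrapped coordinates is forbidden:
#' missing `unwrapped_z` is an error.
#'
#' @param frame a [structure_frame()] carrying `charge`, `unwrapped_z` and
#'   `box_length_z`.
#' @return displacement charge in e.
#' @export
displacement_charge <- function(frame) {
  if (is.null(frame$charge)) stop("frame has no partial charges")
  if (is.null(frame$unwrapped_z)) {
    stop("frame has no unwrapped z-coordinates (wrapped z must not be used)")
  }
  if (is.null(frame$box_length_z)) stop("frame has no box_length_z")
  Lz <- frame$box_length_z
  sum(frame$charge * (frame$unwrapped_z + Lz / 2) / Lz)
}

resolve_target <- function(frame, target) {
  if (is.numeric(target) && is.null(names(target))) return(as.integer(target))
  idx <- select_atoms(frame, resid = target$resid, atom_name = target$atom,
                      resname = target$resname)
  if (length(idx) == 0) {
    cand <- unique(frame$atom_name[frame$resid %in% target$resid])
    stop(sprintf("cannot resolve atoms '%s' in residue(s) %s; available: %s",
                 paste(target$atom, collapse = ","),
                 paste(target$resid, collapse = ","),
                 paste(cand, collapse = " ")))
  }
  idx
}

#' Salt-bridge and group distances
#'
#' Euclidean distances between pairs of atoms or atom groups. Single atoms
#' use their coordinates directly; multi-atom groups use their mass-weighted
#' center of mass (e.g. the distance from an arginine C-zeta to the center
#' of mass of a phenylalanine side chain). Pair endpoints are either raw
#' atom-index vectors or selection specs `list(resid=, atom=)`.
#'
#' @param frame a [structure_frame()].
#' @param pairs list of 2-element lists (endpoint specs).
#' @return named numeric vector of distances (Angstrom), one per pair.
#' @export
salt_bridge_distances <- function(frame, pairs) {
  vapply(pairs, function(pr) {
    ia <- resolve_target(frame, pr[[1]])
    ib <- resolve_target(frame, pr[[2]])
    pa <- if (length(ia) == 1) frame$coords[ia, ] else com(frame, ia)
    pb <- if (length(ib) == 1) frame$coords[ib, ] else com(frame, ib)
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
}

#' Committor-basis distance pairs for a voltage-sensor domain
#'
#' Builds the standard committor feature list from two residue groups: the
#' five S4 sensing arginines and six acidic countercharge residues. It
#' contains every intergroup C-alpha/C-alpha pair plus every pair of an
#' arginine C-zeta with the carboxylate carbon of an acidic residue (C-gamma
#' for aspartate, C-delta for glutamate): `(5 x 6) + (5 x 6) = 60` distances.
#'
#' @param arg_resids residue ids of the sensing arginines.
#' @param acidic_resids residue ids of the acidic countercharges.
#' @param acidic_types one of `"ASP"`/`"GLU"` per acidic residue (controls
#'   C-gamma vs C-delta).
#' @return list of pairs suitable for [salt_bridge_distances()], named
#'   `CA_<i>_<j>` and `SC_<i>_<j>`.
#' @export
committor_distance_pairs <- function(arg_resids = c(217, 223, 226, 229, 232),
                                     acidic_resids = c(129, 136, 151, 164, 183, 186),
                                     acidic_types = c("ASP", "ASP", "ASP", "ASP", "GLU", "ASP")) {
  stopifnot(length(acidic_types) == length(acidic_resids))
  pairs <- list()
  for (r in arg_resids) for (a in acidic_resids) {
    pairs[[sprintf("CA_%d_%d", r, a)]] <-
      list(list(resid = r, atom = "CA"), list(resid = a, atom = "CA"))
  }
  for (r in arg_resids) for (k in seq_along(acidic_resids)) {
    a <- acidic_resids[k]
    carbox <- if (acidic_types[k] == "GLU") "CD" else "CG"
    pairs[[sprintf("SC_%d_%d", r, a)]] <-
      list(list(resid = r, atom = "CZ"), list(resid = a, atom = carbox))
  }
  pairs
}

#' Hydrogen-bond criteria
#'
#' Geometric criteria: maximum donor-acceptor heavy-atom distance and
#' minimum donor-hydrogen-acceptor angle. The angle is measured at the
#' hydrogen (180 degrees = perfectly linear bond).
#'
#' @param max_heavy_distance Angstrom (default 3.5).
#' @param min_angle degrees (default 120).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, min_angle = 120) {
  stopifnot(max_heavy_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_heavy_distance = max_heavy_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds
#'
#' Returns every (donor, hydrogen, acceptor) triple with donor-acceptor
#' distance at most `criteria$max_heavy_distance` and D-H-A angle at least
#' `criteria$min_angle`.
#'
#' @param frame a [structure_frame()].
#' @param donors 2-column matrix of atom indices `(donor, hydrogen)`.
#' @param acceptors vector of acceptor atom indices.
#' @param criteria an [hbond_criteria()].
#' @return data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (possibly 0 rows).
#' @export
hydrogen_bonds <- function(frame, donors, acceptors, criteria = hbond_criteria()) {
  donors <- matrix(as.integer(donors), ncol = 2)
  out <- list()
  for (k in seq_len(nrow(donors))) {
    d <- frame$coords[donors[k, 1], ]
    h <- frame$coords[donors[k, 2], ]
    for (a in acceptors) {
      pa <- frame$coords[a, ]
      dist <- sqrt(sum((d - pa)^2))
      if (dist > criteria$max_heavy_distance) next
      v1 <- d - h; v2 <- pa - h
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= criteria$min_angle) {
        out[[length(out) + 1]] <- data.frame(
          donor = donors[k, 1], hydrogen = donors[k, 2], acceptor = a,
          distance = dist, angle = ang)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  }
  do.call(rbind, out)
}

#' Read a structure from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning a [structure_frame()].
#'
#' @param path PDB file path.
#' @return a [structure_frame()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  structure_frame(
    coords = cbind(at$x, at$y, at$z),
    atom_name = at$elety,
    resid = at$resno,
    resname = at$resid
  )
}

#' Iterate over trajectory frames (DCD or multi-model PDB)
#'
#' Reads trajectory frames against a PDB topology and returns them as a
#' list of [structure_frame()]s. `.dcd` files are read with
#' [bio3d::read.dcd()]; any other extension is treated as a multi-model PDB
#' read with [bio3d::read.pdb()]. The atom counts of topology and
#' trajectory must agree.
#'
#' @param paths character vector of trajectory paths.
#' @param topology PDB path.
#' @return list of [structure_frame()]s.
#' @export
read_trajectory <- function(paths, topology) {
  ref <- read_structure(topology)
  n_atoms <- nrow(ref$coords)
  frames <- list()
  for (p in paths) {
    xyz <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      bio3d::read.dcd(p, verbose = FALSE)
    } else {
      pdb <- bio3d::read.pdb(p, multi = TRUE)
      matrix(pdb$xyz, nrow = nrow(pdb$xyz))
    }
    if (ncol(xyz) != 3 * n_atoms) {
      stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory %d",
                   n_atoms, ncol(xyz) / 3))
    }
    for (i in seq_len(nrow(xyz))) {
      fr <- ref
      fr$coords <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      frames[[length(frames) + 1]] <- fr
    }
  }
  frames
}
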