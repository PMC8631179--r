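# Trajectory analytics: superposition, RMSD, RMSF, cross-correlation,
# geometric hydrogen-bond occupancy. Frames are held in memory as an
# F x N x 3 array in Angstrom; no periodic-boundary handling (inputs are
# assumed already imaged).

#' Construct an in-memory trajectory
#'
#' @param frames Numeric array `F x N x 3` of coordinates, Angstrom (a
#'   single `N x 3` matrix is promoted to one frame).
#' @param masses Atomic masses, amu (default 1 for every atom).
#' @param resid Integer residue index per atom (default: one residue).
#' @param labels Optional atom labels.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(frames, masses = NULL, resid = NULL, labels = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  d <- dim(frames)
  if (length(d) != 3L || d[3] != 3L) stop("'frames' must be F x N x 3")
  n <- d[2]
  masses <- masses %||% rep(1, n)
  resid <- resid %||% rep(1L, n)
  if (length(masses) != n || any(masses <= 0)) stop("bad masses")
  if (length(resid) != n) stop("bad residue map")
  structure(list(frames = frames, masses = as.numeric(masses),
                 resid = as.integer(resid), labels = labels,
                 n_frames = d[1], n_atoms = n),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms,",
      length(unique(x$resid)), "residue(s)\n")
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Uses the `bio3d` PDB parser; each MODEL becomes one frame. Masses are
#' assigned from the element (first letter of the atom name) with a small
#' standard table, defaulting to 12 amu for unknown elements.
#'
#' @param path PDB file path.
#' @return A [trajectory()].
#' @export
read_traj_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                               # n_frames x 3N
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); n <- ncol(xyz) / 3
  frames <- array(0, c(nf, n, 3))
  for (k in 1:3) frames[, , k] <- xyz[, seq(k, by = 3, length.out = n), drop = FALSE]
  elem <- toupper(substr(gsub("[0-9]", "", pdb$atom$elety), 1, 1))
  mtab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
            P = 30.974)
  masses <- unname(ifelse(elem %in% names(mtab), mtab[elem], 12))
  trajectory(frames, masses = masses, resid = pdb$atom$resno,
             labels = pdb$atom$elety)
}

#' Read a whitespace xyz-table trajectory
#'
#' Plain-text dialect: columns `frame`, `atom`, `x`, `y`, `z` (header
#' optional in that order). Frames and atoms must form a complete grid.
#'
#' @param path File path.
#' @param masses,resid Optional per-atom metadata, see [trajectory()].
#' @return A [trajectory()].
#' @export
read_traj_xyz <- function(path, masses = NULL, resid = NULL) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("frame", "atom", "x", "y", "z") %in% colnames(df)))
    df <- utils::read.table(path, header = FALSE,
                            col.names = c("frame", "atom", "x", "y", "z"))
  fr <- sort(unique(df$frame)); at <- sort(unique(df$atom))
  if (nrow(df) != length(fr) * length(at))
    stop("incomplete frame x atom grid in ", path)
  frames <- array(0, c(length(fr), length(at), 3))
  fi <- match(df$frame, fr); ai <- match(df$atom, at)
  for (k in seq_len(nrow(df)))
    frames[fi[k], ai[k], ] <- c(df$x[k], df$y[k], df$z[k])
  trajectory(frames, masses = masses, resid = resid)
}

# optimal rotation (Kabsch, via SVD) mapping moving -> target, both centred
.kabsch <- function(moving, target, w = NULL) {
  w <- w %||% rep(1, nrow(moving))
  H <- t(moving * w) %*% target
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Rigid-body superposition of a trajectory onto a reference
#'
#' Least-squares fits every frame onto the reference over the selected
#' atoms (optimal rotation by the Kabsch/SVD solution, optionally
#' mass-weighted), removing global translation and rotation. The
#' transformation is applied to all atoms; RMSD over the selection can
#' only decrease.
#'
#' @param traj A [trajectory()].
#' @param ref Reference coordinates: `N x 3` matrix or a 1-frame
#'   trajectory (default: first frame of `traj`).
#' @param selection Integer atom indices used for the fit (default: all).
#' @param mass_weighted Weight the fit by atomic masses.
#' @return The aligned [trajectory()].
#' @export
superpose <- function(traj, ref = NULL, selection = NULL,
                      mass_weighted = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- .ref_coords(traj, ref)
  selection <- selection %||% seq_len(traj$n_atoms)
  if (!length(selection)) stop("empty selection")
  if (length(selection) < 3L) stop("need at least 3 atoms to superpose")
  sel_ref <- ref[selection, , drop = FALSE]
  # collinearity guard: rank of centred selection must be >= 2
  cc <- sweep(sel_ref, 2, colMeans(sel_ref))
  if (qr(cc)$rank < 2L) stop("selected reference atoms are collinear")
  w <- if (mass_weighted) traj$masses[selection] else rep(1, length(selection))
  ref_cen <- colSums(sel_ref * w) / sum(w)
  ref_c <- sweep(sel_ref, 2, ref_cen)
  out <- traj$frames
  for (f in seq_len(traj$n_frames)) {
    X <- traj$frames[f, , ]
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    mob <- X[selection, , drop = FALSE]
    cen <- colSums(mob * w) / sum(w)
    R <- .kabsch(sweep(mob, 2, cen), ref_c, w)
    out[f, , ] <- sweep(sweep(X, 2, cen) %*% R, 2, ref_cen, `+`)
  }
  traj$frames <- out
  traj
}

.ref_coords <- function(traj, ref) {
  if (is.null(ref)) {
    r <- traj$frames[1, , ]
    if (is.null(dim(r))) r <- matrix(r, ncol = 3)
    return(r)
  }
  if (inherits(ref, "trajectory")) {
    r <- ref$frames[1, , ]
    if (is.null(dim(r))) r <- matrix(r, ncol = 3)
    ref <- r
  }
  ref <- as.matrix(ref)
  if (ncol(ref) != 3 || nrow(ref) != traj$n_atoms)
    stop("reference does not match the trajectory atoms")
  ref
}

#' Per-frame RMSD against a reference structure
#'
#' Mass-weighted by default:
#' `RMSD(t) = sqrt( sum_i m_i |r_i(t) - r'_i|^2 / sum_i m_i )` over the
#' selection. Set `mass_weighted = FALSE` for the unweighted variant.
#'
#' @inheritParams superpose
#' @param mass_weighted Use atomic masses as weights (default TRUE).
#' @param fit Superpose each frame on the reference first.
#' @return Numeric vector of per-frame RMSD values, Angstrom.
#' @export
rmsd_series <- function(traj, ref = NULL, selection = NULL,
                        mass_weighted = TRUE, fit = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- .ref_coords(traj, ref)
  selection <- selection %||% seq_len(traj$n_atoms)
  if (any(selection < 1 | selection > traj$n_atoms))
    stop("selection out of range")
  if (fit) traj <- superpose(traj, ref, selection, mass_weighted)
  w <- if (mass_weighted) traj$masses[selection] else rep(1, length(selection))
  refs <- ref[selection, , drop = FALSE]
  vapply(seq_len(traj$n_frames), function(f) {
    X <- traj$frames[f, , ]
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    d2 <- rowSums((X[selection, , drop = FALSE] - refs)^2)
    sqrt(sum(w * d2) / sum(w))
  }, 0)
}

#' Root-mean-square fluctuations per atom or residue
#'
#' Atom level: fluctuation of each atom about its time-mean position,
#' `RMSF_i = sqrt( mean_t |r_i(t) - <r_i>|^2 )` (unweighted; pass a
#' static `ref` to measure about a fixed structure instead). Residue
#' level: mass-weighted average of the atomic values over each residue's
#' atoms, which always lies between the residue's extreme atomic values.
#'
#' @param traj A [trajectory()].
#' @param level `"atom"` or `"residue"`.
#' @param ref Optional fixed `N x 3` reference; default is the time mean.
#' @return Named numeric vector of fluctuations, Angstrom.
#' @export
rmsf <- function(traj, level = c("atom", "residue"), ref = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  level <- match.arg(level)
  fr <- traj$frames
  mean_pos <- if (is.null(ref)) apply(fr, c(2, 3), mean) else .ref_coords(traj, ref)
  dev2 <- 0
  for (k in 1:3)
    dev2 <- dev2 + colMeans((fr[, , k, drop = FALSE] -
                               rep(mean_pos[, k], each = traj$n_frames))^2)
  atom_fluct <- sqrt(as.numeric(dev2))
  if (level == "atom") return(atom_fluct)
  res <- sort(unique(traj$resid))
  out <- vapply(res, function(r) {
    i <- which(traj$resid == r)
    if (!length(i)) stop("empty residue ", r)
    sum(atom_fluct[i] * traj$masses[i]) / sum(traj$masses[i])
  }, 0)
  setNames(out, res)
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of atomic displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with
#' `dr_i = r_i(t) - <r_i>` and the scalar product over x, y, z. The
#' trajectory should be superposed first (set `fit = TRUE` to do it
#' here); values lie in [-1, 1] with a unit diagonal. Atoms with zero
#' positional variance give undefined entries, reported as `NA` with a
#' warning rather than 0.
#'
#' @inheritParams superpose
#' @param fit Superpose on the selection before computing.
#' @return `n x n` matrix of class `"dccm_matrix"` for the selected atoms.
#' @export
dccm <- function(traj, selection = NULL, fit = FALSE, ref = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  selection <- selection %||% seq_len(traj$n_atoms)
  if (fit) traj <- superpose(traj, ref, selection)
  n <- length(selection)
  fr <- traj$frames[, selection, , drop = FALSE]
  cmat <- matrix(0, n, n)
  for (k in 1:3) {
    Xk <- fr[, , k]
    if (is.null(dim(Xk))) Xk <- matrix(Xk, nrow = traj$n_frames)
    Xk <- sweep(Xk, 2, colMeans(Xk))
    cmat <- cmat + crossprod(Xk) / traj$n_frames
  }
  v <- diag(cmat)
  zero <- v <= 0
  if (any(zero)) warning("zero-variance atom(s): entries set to NA")
  den <- sqrt(outer(v, v))
  C <- cmat / den
  C[zero, ] <- NA_real_; C[, zero] <- NA_real_
  # clip tiny floating excursions only
  C[!is.na(C) & C > 1 & C <= 1 + 1e-12] <- 1
  C[!is.na(C) & C < -1 & C >= -1 - 1e-12] <- -1
  diag(C)[!zero] <- 1
  structure(C, class = c("dccm_matrix", "matrix"))
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("Cross-correlation matrix,", nrow(x), "x", ncol(x), "\n")
  print(signif(unclass(x), 3))
  invisible(x)
}

#' Geometric hydrogen-bond occupancy
#'
#' A donor-hydrogen-acceptor triple counts as bonded in a frame when the
#' distance is below `dist_cutoff` (default 3.5 A, measured between the
#' donor and acceptor heavy atoms; set `distance = "HA"` for the
#' hydrogen-acceptor convention) and the D-H...A angle is strictly
#' between `angle_min` and `angle_max` degrees (120 and 180: an exactly
#' linear 180-degree geometry is excluded by the strict inequality).
#'
#' @param traj A [trajectory()].
#' @param donors Integer matrix or data frame with columns `D` (donor
#'   heavy atom) and `H` (its hydrogen), one row per donor.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param dist_cutoff Distance criterion, Angstrom.
#' @param angle_min,angle_max Angle window, degrees (strict inequalities).
#' @param distance `"DA"` (donor-acceptor, default) or `"HA"`.
#' @return List with `pairs` (data frame: donor, hydrogen, acceptor,
#'   occupancy = fraction of frames bonded) and `total` (mean number of
#'   bonds per frame).
#' @export
hbond_occupancy <- function(traj, donors, acceptors, dist_cutoff = 3.5,
                            angle_min = 120, angle_max = 180,
                            distance = c("DA", "HA")) {
  stopifnot(inherits(traj, "trajectory"))
  distance <- match.arg(distance)
  donors <- as.matrix(donors)
  if (ncol(donors) != 2L) stop("'donors' needs columns D and H")
  pairs <- expand.grid(d = seq_len(nrow(donors)), a = seq_along(acceptors))
  occ <- numeric(nrow(pairs)); keep <- rep(TRUE, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    D <- donors[pairs$d[p], 1]; H <- donors[pairs$d[p], 2]
    A <- acceptors[pairs$a[p]]
    if (A == D || A == H) { keep[p] <- FALSE; next }
    hits <- 0L; bad <- FALSE
    for (f in seq_len(traj$n_frames)) {
      rd <- traj$frames[f, D, ]; rh <- traj$frames[f, H, ]
      ra <- traj$frames[f, A, ]
      v1 <- rd - rh; v2 <- ra - rh
      n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
      if (n1 == 0 || n2 == 0) { bad <- TRUE; break }
      dist <- if (distance == "DA") sqrt(sum((rd - ra)^2)) else n2
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
      if (dist < dist_cutoff && ang > angle_min && ang < angle_max)
        hits <- hits + 1L
    }
    if (bad) {
      warning("overlapping atoms in pair D=", D, " A=", A, "; pair skipped")
      keep[p] <- FALSE
    } else occ[p] <- hits / traj$n_frames
  }
  pairs <- pairs[keep, , drop = FALSE]
  res <- data.frame(donor = donors[pairs$d, 1], hydrogen = donors[pairs$d, 2],
                    acceptor = acceptors[pairs$a], occupancy = occ[keep])
  list(pairs = res, total = sum(res$occupancy))
}
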