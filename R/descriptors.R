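# Global structural descriptors: superposition/RMSD, radius of gyration,
# per-residue RMSF and the Best-Hummer-Eaton fraction of native contacts.
# Internals work in Angstrom; the descriptor series report nm (the convention
# of the GROMACS analysis modules these operations mirror).

new_descriptor_series <- function(name, values, times, units) {
  structure(list(name = name, values = as.numeric(values),
                 times = as.numeric(times), units = units),
            class = "DescriptorSeries")
}

#' @export
print.DescriptorSeries <- function(x, ...) {
  cat("<DescriptorSeries> ", x$name, " [", x$units, "], ", length(x$values),
      " frames; mean = ", signif(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.DescriptorSeries <- function(x, ...) {
  data.frame(time_ps = x$times, value = x$values)
}

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the weighted
#' RMSD between `R x + t` (for `x` in `mobile`) and `reference`. The
#' reflection branch of the SVD solution (det = -1) is corrected by flipping
#' the sign of the smallest singular vector, so the rotation is always proper.
#'
#' @param mobile,reference `N x 3` coordinate matrices (Angstrom).
#' @param weights Optional non-negative weights, length `N`, not all zero.
#' @return List of class `SuperpositionResult`: `rotation` (3x3, det +1),
#'   `translation` (length 3, Angstrom) and `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  w <- weights %||% rep(1, n)
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, not all zero")
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)

  sv_p <- svd(p * sqrt(w))$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    stop("degenerate geometry: points are collinear, rotation is underdetermined")
  }

  h <- crossprod(p * w, q)           # 3x3 covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - q)^2)))
  structure(list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "SuperpositionResult")
}

apply_superposition <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD time series relative to a reference frame
#'
#' Each frame is optimally superposed onto the reference frame on the given
#' selection before computing the RMSD over that selection. The default
#' selection is the C-alpha trace; use `"backbone"` for N/CA/C/O.
#'
#' @param traj A [trajectory()] object.
#' @param selection Selector string (see [select_atoms()]).
#' @param ref_frame Reference frame index (default 1, the initial
#'   conformation).
#' @param mass_weighted Weight the fit and RMSD by atomic mass.
#' @return A `DescriptorSeries` named `"RMSD"` in nm.
#' @export
rmsd_series <- function(traj, selection = "ca", ref_frame = 1L,
                        mass_weighted = FALSE) {
  idx <- select_atoms(traj$topology, selection)
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  stopifnot(ref_frame >= 1L, ref_frame <= n_frames(traj))
  w <- if (mass_weighted) traj$topology$atoms$mass[idx] else NULL
  ref <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    kabsch(frame_coords(traj, k)[idx, , drop = FALSE], ref, w)$rmsd
  }, numeric(1))
  new_descriptor_series("RMSD", vals / ANGSTROM_PER_NM, traj$times, "nm")
}

#' Radius of gyration time series
#'
#' \eqn{R_g = \sqrt{\sum_i m_i \|r_i - r_{com}\|^2 / \sum_i m_i}}, the
#' mass-weighted RMS distance of the selected atoms from their center of mass
#' (global compactness). `mass_weighted = FALSE` sets all masses equal.
#'
#' @inheritParams rmsd_series
#' @return A `DescriptorSeries` named `"Rg"` in nm.
#' @export
radius_of_gyration_series <- function(traj, selection = "protein",
                                      mass_weighted = TRUE) {
  idx <- select_atoms(traj$topology, selection)
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  m <- if (mass_weighted) traj$topology$atoms$mass[idx] else rep(1, length(idx))
  m <- m / sum(m)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    x <- frame_coords(traj, k)[idx, , drop = FALSE]
    com <- colSums(x * m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)))
  }, numeric(1))
  new_descriptor_series("Rg", vals / ANGSTROM_PER_NM, traj$times, "nm")
}

#' Per-residue root-mean-square fluctuation
#'
#' Every frame is superposed onto the reference frame on the selection; the
#' RMSF of each selected atom is then the RMS deviation from its
#' time-averaged position, averaged per residue (the default `ca` selection
#' gives one atom per residue).
#'
#' @inheritParams rmsd_series
#' @return Data frame of class `RMSFProfile` with columns `chain`, `resid`,
#'   `resname`, `rmsf` (nm).
#' @export
rmsf_profile <- function(traj, selection = "ca", ref_frame = 1L) {
  if (n_frames(traj) < 2L) {
    stop("RMSF is undefined for a single-frame trajectory")
  }
  idx <- select_atoms(traj$topology, selection)
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  ref <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  nf <- n_frames(traj)
  fitted <- array(NA_real_, dim = c(nf, length(idx), 3L))
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)[idx, , drop = FALSE]
    fitted[k, , ] <- apply_superposition(x, kabsch(x, ref))
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- vapply(seq_along(idx), function(j) {
    mean(rowSums(sweep(matrix(fitted[, j, ], ncol = 3L), 2, mean_pos[j, ])^2))
  }, numeric(1))
  rmsf_atom <- sqrt(dev2) / ANGSTROM_PER_NM

  a <- traj$topology$atoms[idx, , drop = FALSE]
  key <- factor(paste(a$chain, a$resid, sep = "\r"),
                levels = unique(paste(a$chain, a$resid, sep = "\r")))
  first <- !duplicated(key)
  out <- data.frame(
    chain = a$chain[first], resid = a$resid[first], resname = a$resname[first],
    rmsf = as.numeric(tapply(rmsf_atom, key, mean)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' Native contact set of a reference conformation
#'
#' All heavy-atom pairs between residues separated by more than `min_seq_sep`
#' in sequence whose reference distance is at most `cutoff` define the native
#' contact set; the Best-Hummer-Eaton switching parameters are attached
#' (`beta` = 5 per Angstrom, `lambda` = 1.8 by default).
#'
#' @param traj A [trajectory()] object; `ref_frame` names the native frame.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param min_seq_sep Contacts require residue separation strictly greater
#'   than this (pairs on different chains always qualify).
#' @param ref_frame Native (reference) frame index.
#' @param selection Atom set that can form contacts.
#' @param beta,lambda Switching-function parameters.
#' @return List of class `NativeContactSet`: `pairs` (2-column atom-index
#'   matrix), `r0` (reference distances, Angstrom), `beta`, `lambda`,
#'   `cutoff`, `min_seq_sep`.
#' @export
native_contacts <- function(traj, cutoff = 4.5, min_seq_sep = 3L,
                            ref_frame = 1L, selection = "heavy",
                            beta = 5, lambda = 1.8) {
  idx <- select_atoms(traj$topology, selection)
  if (!length(idx)) stop("selection '", selection, "' matches no atoms")
  x <- frame_coords(traj, ref_frame)[idx, , drop = FALSE]
  a <- traj$topology$atoms[idx, , drop = FALSE]

  d <- cross_dist(x, x)
  sep_ok <- outer(a$resid, a$resid, function(i, j) abs(i - j) > min_seq_sep) |
    outer(a$chain, a$chain, "!=")
  hit <- which(upper.tri(d) & d <= cutoff & sep_ok, arr.ind = TRUE)
  pairs <- cbind(i = idx[hit[, 1]], j = idx[hit[, 2]])
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, 2:1]
  structure(list(pairs = pairs, r0 = d[hit], beta = beta, lambda = lambda,
                 cutoff = cutoff, min_seq_sep = min_seq_sep),
            class = "NativeContactSet")
}

#' @export
print.NativeContactSet <- function(x, ...) {
  cat("<NativeContactSet> ", nrow(x$pairs), " pairs; beta = ", x$beta,
      " 1/A, lambda = ", x$lambda, ", cutoff = ", x$cutoff, " A\n", sep = "")
  invisible(x)
}

#' Fraction of native contacts (Q) time series
#'
#' Per frame, \eqn{Q = |S|^{-1} \sum_{(i,j) \in S} [1 + \exp(\beta (r_{ij} -
#' \lambda r^0_{ij}))]^{-1}} over the native contact set S. The smooth
#' switching function gives Q slightly below 1 even on the native frame, so
#' the raw series is the default and `normalize = TRUE` divides by Q of the
#' reference frame.
#'
#' @param traj A [trajectory()] object.
#' @param contacts A [native_contacts()] set (non-empty).
#' @param normalize Divide by Q of `ref_frame`.
#' @param ref_frame Frame used for normalization.
#' @return A `DescriptorSeries` named `"Q"` (dimensionless).
#' @export
q_series <- function(traj, contacts, normalize = FALSE, ref_frame = 1L) {
  stopifnot(inherits(contacts, "NativeContactSet"))
  if (!nrow(contacts$pairs)) stop("empty native contact set")
  b <- contacts$beta; lr0 <- contacts$lambda * contacts$r0
  qf <- function(k) {
    x <- frame_coords(traj, k)
    dx <- x[contacts$pairs[, 1], , drop = FALSE] -
      x[contacts$pairs[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dx^2))
    mean(1 / (1 + exp(b * (r - lr0))))
  }
  vals <- vapply(seq_len(n_frames(traj)), qf, numeric(1))
  if (normalize) vals <- vals / qf(ref_frame)
  new_descriptor_series("Q", vals, traj$times, "fraction")
}
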