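# Seeded synthetic structures and trajectories with known ground truth.
# These stand in for microsecond MD so every analysis stage has a
# parameter-recovery test at desk scale: rigid-body motion (zero RMSD),
# stationary Gaussian noise (RMSF = sigma * sqrt(3)), progressive expansion
# (Rg scaling, Q decay), intermittent charged contacts (salt-bridge
# frequency = p) and engineered protein-water geometries (HBps counts).
#
# Toy residues carry only the atoms the analyses need: backbone N/CA/C/O,
# amide H, CB, and single charged side-chain termini (Lys NZ, Arg NH1,
# Asp OD1, Glu OE1). No force field, thermostat or actual dynamics.

.BOND <- list(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
              N_H = 1.01, CA_CB = 1.53)
.ANGLE <- list(C_N_CA = 121.7, N_CA_C = 111.2, CA_C_N = 116.2, CA_C_O = 120.8)

.charged_terminus <- c(LYS = "NZ", ARG = "NH1", ASP = "OD1", GLU = "OE1")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Build a polypeptide backbone with per-residue dihedrals by internal-
# coordinate chain extension. phi/psi are vectors (recycled); omega fixed
# trans. Returns list(atoms = data.frame, coords = matrix).
build_backbone <- function(sequence, phi, psi, omega = 180, chain = "A",
                           resid_start = 1L) {
  aa1 <- if (length(sequence) == 1L && nchar(sequence) > 1L) {
    strsplit(sequence, "")[[1]]
  } else sequence
  n <- length(aa1)
  resnames <- names(.aa3_to_1)[match(toupper(aa1), .aa3_to_1)]
  if (anyNA(resnames)) stop("unknown one-letter code in sequence")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)

  pos <- list()  # per residue: named list of atom coords
  # seed residue: N at origin, CA along x, C in the xy-plane
  N1 <- c(0, 0, 0)
  CA1 <- c(.BOND$N_CA, 0, 0)
  ang <- .ANGLE$N_CA_C * pi / 180
  C1 <- CA1 + .BOND$CA_C * c(-cos(ang), sin(ang), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)

  for (i in seq_len(n)) {
    p <- pos[[i]]
    if (i < n) {
      Nn <- place_atom(p$N, p$CA, p$C, .BOND$C_N, .ANGLE$CA_C_N, psi[i])
      CAn <- place_atom(p$CA, p$C, Nn, .BOND$N_CA, .ANGLE$C_N_CA, omega)
      Cn <- place_atom(p$C, Nn, CAn, .BOND$CA_C, .ANGLE$N_CA_C, phi[i + 1])
      pos[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
      # carbonyl O anti to the next amide N in the peptide plane
      pos[[i]]$O <- place_atom(Nn, p$CA, p$C, .BOND$C_O, .ANGLE$CA_C_O,
                               180)
    } else {
      pos[[i]]$O <- place_atom(p$N, p$CA, p$C, .BOND$C_O, .ANGLE$CA_C_O,
                               psi[i] + 180)
    }
  }
  # amide hydrogens (external bisector, anti to the previous carbonyl) and
  # side-chain stubs
  for (i in seq_len(n)) {
    p <- pos[[i]]
    if (i > 1L && resnames[i] != "PRO") {
      u <- -(unitv(pos[[i - 1]]$C - p$N) + unitv(p$CA - p$N))
      pos[[i]]$H <- p$N + .BOND$N_H * unitv(u)
    }
    if (resnames[i] != "GLY") {
      cb <- place_atom(p$N, p$C, p$CA, .BOND$CA_CB, 110.1, -122)
      pos[[i]]$CB <- cb
      term <- .charged_terminus[resnames[i]]
      if (!is.na(term)) {
        # charged terminus extended along CA->CB; real rotamers are out of
        # scope, generators that need exact pair distances reposition it
        pos[[i]][[term]] <- p$CA + 3.5 * unitv(cb - p$CA)
      }
    }
  }

  rows <- list(); xyz <- list(); serial <- 0L
  for (i in seq_len(n)) {
    for (nm in names(pos[[i]])) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        element = substr(nm, 1, 1), resname = resnames[i],
        resid = resid_start + i - 1L, chain = chain,
        stringsAsFactors = FALSE)
      xyz[[serial]] <- pos[[i]][[nm]]
    }
  }
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, xyz))
}

finish_structure <- function(atoms, coords) {
  atoms$serial <- seq_len(nrow(atoms))
  top <- topology(atoms)
  list(topology = top, coords = coords,
       trajectory = trajectory(top, coords))
}

#' Ideal alpha-helix fixture
#'
#' Poly-peptide with phi = -57, psi = -47, omega = 180 and ideal bond
#' geometry; amide hydrogens included. Interior i -> i+4 O...N distances
#' come out near 2.9-3.1 Angstrom.
#'
#' @param n_residues Number of residues (>= 4).
#' @param sequence One-letter sequence (default poly-Ala).
#' @return List with `topology`, `coords` (N x 3 matrix) and a single-frame
#'   `trajectory`.
#' @export
build_ideal_helix <- function(n_residues, sequence = NULL) {
  if (n_residues < 4L) stop("an ideal helix needs at least 4 residues")
  seq1 <- sequence %||% strrep("A", n_residues)
  bb <- build_backbone(seq1, phi = -57, psi = -47)
  finish_structure(bb$atoms, bb$coords)
}

# Rigid transform placing a 180-degree-flipped copy of an ideal strand
# alongside the original in antiparallel H-bond registry: residue i of
# strand 1 pairs with copy residue n+1-i, with O...N driven to 2.9 and
# O...H to 1.92 Angstrom (near-linear N-H...O) by a deterministic
# Nelder-Mead fit from fixed starts. Returns a function mapping untransformed
# strand coordinates to their placed copy, so a second strand with a
# different sequence but the same backbone can reuse the fit.
.ap_fit_cache <- new.env(parent = emptyenv())

fit_antiparallel_copy <- function(s1) {
  n <- max(s1$atoms$resid) - min(s1$atoms$resid) + 1L
  r0 <- min(s1$atoms$resid) - 1L
  # the fit depends only on the (deterministic) ideal-strand backbone, so
  # cache per strand length
  cache_key <- as.character(n)
  if (!is.null(.ap_fit_cache[[cache_key]])) return(.ap_fit_cache[[cache_key]])
  flip <- diag(c(-1, 1, -1))
  x2_0 <- s1$coords %*% flip
  get <- function(x, nm, r) {
    i <- which(s1$atoms$name == nm & s1$atoms$resid == r + r0)
    if (length(i)) x[i, ] else NULL
  }
  pairs <- cbind(seq(1, n, 2), n + 1 - seq(1, n, 2))
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    rot <- rotation_about_axis(if (th < 1e-12) c(0, 0, 1) else par[1:3], th)
    x2 <- sweep(x2_0 %*% t(rot), 2, par[4:6], "+")
    s <- 0
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      h2 <- get(x2, "H", j); h1 <- get(s1$coords, "H", i)
      if (!is.null(h2)) {
        s <- s + (vnorm(get(s1$coords, "O", i) - get(x2, "N", j)) - 2.9)^2 +
          (vnorm(get(s1$coords, "O", i) - h2) - 1.92)^2
      }
      if (!is.null(h1)) {
        s <- s + (vnorm(get(s1$coords, "N", i) - get(x2, "O", j)) - 2.9)^2 +
          (vnorm(h1 - get(x2, "O", j)) - 1.92)^2
      }
    }
    # weak pleating target: paired C-alpha spacing near the 4.8-5.0 A of
    # real antiparallel sheets
    for (i in seq_len(n)) {
      s <- s + 0.3 * (vnorm(get(s1$coords, "CA", i) -
                              get(x2, "CA", n + 1 - i)) - 5.0)^2
    }
    d <- cross_dist(s1$coords, x2)
    s + 10 * sum(pmax(0, 2.2 - d)^2)
  }
  best <- NULL
  for (start in list(c(0, 0, 0, 0, 4.8, 0), c(0, 0, 0, 0, -4.8, 0),
                     c(0, 0, 0, 3, 4.8, 0), c(0, 0, 0, -3, 0, -4.8),
                     c(0.5, 0.5, 0.5, 0, 4.8, 0))) {
    r <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 8000, reltol = 1e-13))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 8000, reltol = 1e-13))
    if (is.null(best) || r$value < best$value) best <- r
  }
  th <- sqrt(sum(best$par[1:3]^2))
  rot <- rotation_about_axis(if (th < 1e-12) c(0, 0, 1) else best$par[1:3], th)
  shift <- best$par[4:6]
  out <- function(x) sweep((x %*% flip) %*% t(rot), 2, shift, "+")
  .ap_fit_cache[[cache_key]] <- out
  out
}

#' Ideal antiparallel beta-hairpin fixture
#'
#' Two ideal strands (phi = -139, psi = +135) in one chain: the second
#' strand is a rigid 180-degree flip of the first, fitted so the
#' inter-strand hydrogen-bond registry pairs residue i with residue
#' 2n+2-i at O...N distances of about 2.9 Angstrom. The strands are
#' covalently unconnected (a flagged chain gap stands in for the turn).
#'
#' @param n_per_strand Residues per strand (>= 3).
#' @return As [build_ideal_helix()].
#' @export
build_beta_hairpin <- function(n_per_strand) {
  if (n_per_strand < 3L) stop("a hairpin strand needs at least 3 residues")
  s1 <- build_backbone(strrep("A", n_per_strand), phi = -139, psi = 135)
  x2 <- fit_antiparallel_copy(s1)(s1$coords)
  a2 <- s1$atoms
  a2$resid <- a2$resid + n_per_strand + 1L  # numbering gap marks the turn
  atoms <- rbind(s1$atoms, a2)
  finish_structure(atoms, rbind(s1$coords, x2))
}

#' Toy alpha/beta protein with placed charged pairs
#'
#' Helix + hairpin joined in one chain (mimicking an alpha/beta fold at toy
#' scale), with Lys/Arg/Asp/Glu residues whose charged side-chain termini
#' are placed at configured distances for salt-bridge tests.
#'
#' @param n_helix,n_per_strand Segment sizes.
#' @param charge_pairs List of `list(basic_resid, acidic_resid, distance)`
#'   entries; the named residues must be Lys/Arg and Asp/Glu in `sequence`.
#' @param sequence Optional one-letter sequence covering all
#'   `n_helix + 2 * n_per_strand` residues.
#' @return As [build_ideal_helix()]; atoms closer than 0.8 Angstrom raise an
#'   error.
#' @export
build_toy_protein <- function(n_helix = 8, n_per_strand = 4,
                              charge_pairs = list(), sequence = NULL) {
  n_total <- n_helix + 2L * n_per_strand
  seq1 <- sequence %||% strrep("A", n_total)
  if (nchar(seq1) != n_total) stop("sequence must cover ", n_total, " residues")
  hx <- build_backbone(substr(seq1, 1, n_helix), phi = -57, psi = -47)
  hp_seq <- substr(seq1, n_helix + 1, n_total)
  s1 <- build_backbone(substr(hp_seq, 1, n_per_strand), phi = -139, psi = 135,
                       resid_start = n_helix + 1L)
  place_copy <- fit_antiparallel_copy(s1)
  # strand 2 shares the ideal-strand backbone, so the fitted transform
  # applies to its own (sequence-specific) atom set
  s2 <- build_backbone(substr(hp_seq, n_per_strand + 1, 2 * n_per_strand),
                       phi = -139, psi = 135,
                       resid_start = n_helix + n_per_strand + 1L)
  x2 <- place_copy(s2$coords)

  # park the hairpin well clear of the helix
  hp_atoms <- rbind(s1$atoms, s2$atoms)
  hp_xyz <- sweep(rbind(s1$coords, x2), 2, c(0, 14, 0), "+")
  atoms <- rbind(hx$atoms, hp_atoms)
  xyz <- rbind(hx$coords, hp_xyz)

  # reposition charged termini to the configured pair distances
  for (cp in charge_pairs) {
    bi <- which(atoms$resid == cp$basic_resid)
    ai <- which(atoms$resid == cp$acidic_resid)
    b_term <- bi[atoms$name[bi] %in% c("NZ", "NH1")]
    a_term <- ai[atoms$name[ai] %in% c("OD1", "OE1")]
    if (!length(b_term) || !length(a_term)) {
      stop("charge pair (", cp$basic_resid, ", ", cp$acidic_resid,
           ") needs Lys/Arg and Asp/Glu residues at those positions")
    }
    ca_b <- xyz[bi[atoms$name[bi] == "CA"], ]
    ca_a <- xyz[ai[atoms$name[ai] == "CA"], ]
    u <- unitv(ca_a - ca_b)
    xyz[b_term, ] <- ca_b + 2.0 * u
    xyz[a_term, ] <- xyz[b_term, ] + cp$distance * u
  }

  d <- cross_dist(xyz, xyz); diag(d) <- Inf
  if (min(d) < 0.8) stop("overlapping atoms in toy protein (min distance ",
                         round(min(d), 2), " A)")
  finish_structure(atoms, xyz)
}

#' Rigid-body control trajectory
#'
#' Each frame is a random proper rotation plus translation of the input
#' conformation: internal geometry is exactly preserved, so RMSD, Rg, Q and
#' RMSF ground truths are known (0 / constant).
#'
#' @param struct A structure from the builders above (or any list with
#'   `topology` and `coords`).
#' @param n_frames Number of frames.
#' @param seed RNG seed (full determinism under a fixed seed).
#' @return A [trajectory()] object.
#' @export
make_rigid_trajectory <- function(struct, n_frames, seed = 1L) {
  x0 <- struct$coords
  with_seed(seed, {
    coords <- array(NA_real_, dim = c(n_frames, nrow(x0), 3L))
    for (k in seq_len(n_frames)) {
      rot <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      shift <- stats::runif(3, -10, 10)
      coords[k, , ] <- sweep(x0 %*% t(rot), 2, shift, "+")
    }
    trajectory(struct$topology, coords)
  })
}

#' Stationary Gaussian-fluctuation trajectory
#'
#' Adds iid Gaussian displacements (per coordinate, per frame) about the
#' fixed input positions, with a per-residue standard deviation profile.
#' Ground truth: RMSF of residue i -> sigma_i * sqrt(3) for large F.
#'
#' @param struct Structure with `topology` and `coords`.
#' @param sigma_profile Per-residue sigma in Angstrom (recycled over
#'   residues in residue-table order).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return A [trajectory()] object.
#' @export
make_fluctuation_trajectory <- function(struct, sigma_profile, n_frames,
                                        seed = 1L) {
  top <- struct$topology
  sig_res <- rep_len(sigma_profile, nrow(top$residues))
  res_of_atom <- findInterval(seq_len(n_atoms(top)), top$residues$first)
  sig_atom <- sig_res[res_of_atom]
  x0 <- struct$coords
  with_seed(seed, {
    noise <- stats::rnorm(n_frames * nrow(x0) * 3L) *
      rep(sig_atom, each = n_frames)
    coords <- array(noise, dim = c(n_frames, nrow(x0), 3L))
    coords <- coords + rep(x0, each = n_frames)
    trajectory(top, coords)
  })
}

#' Progressive-expansion (unfolding) trajectory
#'
#' Frame t scales all deviations from the center of mass by `schedule[t]`
#' (non-decreasing schedules emulate thermal unfolding: monotone Rg rise and
#' Q decay) plus a small seeded jitter.
#'
#' @param struct Structure with `topology` and `coords`.
#' @param schedule Per-frame scale factors (>= 1 for unfolding).
#' @param jitter Jitter sigma in Angstrom (default 0.02).
#' @param seed RNG seed.
#' @return A [trajectory()] object.
#' @export
make_unfolding_trajectory <- function(struct, schedule, jitter = 0.02,
                                      seed = 1L) {
  x0 <- struct$coords
  m <- struct$topology$atoms$mass
  com <- colSums(x0 * (m / sum(m)))
  dev <- sweep(x0, 2, com)
  with_seed(seed, {
    coords <- array(NA_real_, dim = c(length(schedule), nrow(x0), 3L))
    for (k in seq_along(schedule)) {
      coords[k, , ] <- sweep(schedule[k] * dev, 2, com, "+") +
        stats::rnorm(length(x0), sd = jitter)
    }
    trajectory(struct$topology, coords)
  })
}

#' Intermittent-contact trajectory (salt-bridge frequency ground truth)
#'
#' The charged pair is inside the salt-bridge cutoff in exactly
#' `round(p * n_frames)` frames (placed at `r_on`), and at `r_off`
#' elsewhere; which frames are "on" is a seeded draw. All other atoms are
#' static.
#'
#' @param struct Structure containing the pair (e.g. [build_toy_protein()]).
#' @param basic_resid,acidic_resid Residue numbers of the pair.
#' @param p Target presence fraction in `[0, 1]`.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param r_on,r_off Pair distance in present/absent frames (Angstrom).
#' @return A [trajectory()] object.
#' @export
make_contact_trajectory <- function(struct, basic_resid, acidic_resid, p,
                                    n_frames, seed = 1L, r_on = 3.5,
                                    r_off = 6.0) {
  stopifnot(p >= 0, p <= 1)
  atoms <- struct$topology$atoms
  bi <- which(atoms$resid == basic_resid &
                atoms$name %in% c("NZ", "NE", "NH1", "NH2"))
  ai <- which(atoms$resid == acidic_resid &
                atoms$name %in% c("OD1", "OD2", "OE1", "OE2"))
  if (!length(bi) || !length(ai)) {
    stop("structure lacks charged termini for residues ", basic_resid,
         " / ", acidic_resid)
  }
  bi <- bi[1]; ai <- ai[1]
  x0 <- struct$coords
  u <- unitv(x0[ai, ] - x0[bi, ])
  n_on <- round(p * n_frames)
  with_seed(seed, {
    on_frames <- if (n_on > 0) sort(sample.int(n_frames, n_on)) else integer(0)
    coords <- array(rep(x0, each = n_frames), dim = c(n_frames, nrow(x0), 3L))
    for (k in seq_len(n_frames)) {
      r <- if (k %in% on_frames) r_on else r_off
      coords[k, bi, ] <- x0[ai, ] - r * u
    }
    trajectory(struct$topology, coords)
  })
}

#' Add an explicit water shell with engineered hydrogen-bond geometries
#'
#' Each plan entry places a 3-site water donating a hydrogen bond to a named
#' protein acceptor atom (water O at `distance` from the acceptor, one O-H
#' pointing straight at it, so both the 3.5-Angstrom and 30-degree criteria
#' hold). `n_random` further waters are scattered beyond 6 Angstrom from the
#' protein.
#'
#' @param struct Structure with `topology` and `coords`.
#' @param water_plan List of `list(resid, atom, distance)` entries
#'   (`distance` defaults to 2.9).
#' @param n_random Count of far, non-bonding waters.
#' @param seed RNG seed.
#' @return A new structure list (`topology`, `coords`, `trajectory`).
#' @export
add_water_shell <- function(struct, water_plan = list(), n_random = 0,
                            seed = 1L) {
  atoms <- struct$topology$atoms
  xyz <- struct$coords
  prot_center <- colMeans(xyz)
  wat_rows <- list(); wat_xyz <- list()
  add_water <- function(o, h1_dir, wid) {
    h1 <- o + 0.9572 * unitv(h1_dir)
    perp <- cross3(h1_dir, if (abs(h1_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    rot <- rotation_about_axis(perp, 104.52 * pi / 180)
    h2 <- o + 0.9572 * as.numeric(rot %*% unitv(h1_dir))
    list(
      data.frame(serial = 0L, name = c("OW", "HW1", "HW2"),
                 element = c("O", "H", "H"), resname = "HOH",
                 resid = wid, chain = "W", stringsAsFactors = FALSE),
      rbind(o, h1, h2))
  }
  wid <- max(atoms$resid) + 1L
  for (entry in water_plan) {
    tgt <- which(atoms$resid == entry$resid & atoms$name == entry$atom)
    if (!length(tgt)) stop("no atom ", entry$atom, " in residue ", entry$resid)
    a_pos <- xyz[tgt[1], ]
    d <- entry$distance %||% 2.9
    o <- a_pos + d * unitv(a_pos - prot_center)
    w <- add_water(o, a_pos - o, wid)
    if (min(cross_dist(w[[2]], xyz)) < 0.8) {
      stop("engineered water overlaps the protein")
    }
    wat_rows[[length(wat_rows) + 1L]] <- w[[1]]
    wat_xyz[[length(wat_xyz) + 1L]] <- w[[2]]
    wid <- wid + 1L
  }
  if (n_random > 0) {
    with_seed(seed, {
      placed <- 0L
      while (placed < n_random) {
        dir <- stats::rnorm(3)
        o <- prot_center + (max(cross_dist(matrix(prot_center, 1), xyz)) +
                              stats::runif(1, 6.5, 12)) * unitv(dir)
        w <- add_water(o, stats::rnorm(3), wid)
        wat_rows[[length(wat_rows) + 1L]] <- w[[1]]
        wat_xyz[[length(wat_xyz) + 1L]] <- w[[2]]
        wid <- wid + 1L
        placed <- placed + 1L
      }
    })
  }
  all_atoms <- rbind(atoms[, c("serial", "name", "element", "resname",
                               "resid", "chain")],
                     do.call(rbind, wat_rows))
  finish_structure(all_atoms, rbind(xyz, do.call(rbind, wat_xyz)))
}
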