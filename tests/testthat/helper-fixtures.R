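# Shared fixture builders and independent brute-force oracles. The oracles
# are deliberately plain double loops: they share no code path with the
# package's vectorized implementations.

# Bare topology from positional atom specs: list(name, element, resname,
# resid) per atom.
mk_topology <- function(specs) {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(serial = i, name = s$name, element = s$element,
               resname = s$resname, resid = s$resid, chain = s$chain %||% "A",
               stringsAsFactors = FALSE)
  })
  topology(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random hydrogen-bond fixture: n_donor donors (N with one H at 1.0 A in a
# random direction), n_acc acceptor oxygens, uniformly placed in a box.
random_hb_fixture <- function(n_donor, n_acc, box = 10) {
  specs <- list(); xyz <- list(); rid <- 0L
  for (i in seq_len(n_donor)) {
    rid <- rid + 1L
    d <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    specs <- c(specs, list(
      list(name = "N", element = "N", resname = "ALA", resid = rid),
      list(name = "H", element = "H", resname = "ALA", resid = rid)))
    xyz <- c(xyz, list(d, d + u))
  }
  for (i in seq_len(n_acc)) {
    rid <- rid + 1L
    specs <- c(specs, list(
      list(name = "O", element = "O", resname = "ALA", resid = rid)))
    xyz <- c(xyz, list(runif(3, 0, box)))
  }
  top <- mk_topology(specs)
  list(traj = trajectory(top, do.call(rbind, xyz)), n_donor = n_donor)
}

# Scalar-loop hydrogen-bond oracle (angle at the donor).
oracle_hbonds <- function(traj, donor_idx, acc_idx, r_max = 3.5,
                          theta_max = 30) {
  x <- frame_coords(traj, 1)
  a <- traj$topology$atoms
  hits <- 0L
  for (d in donor_idx) {
    hs <- c()
    for (h in which(toupper(a$element) == "H")) {
      if (sqrt(sum((x[h, ] - x[d, ])^2)) <= 1.25) hs <- c(hs, h)
    }
    for (acc in acc_idx) {
      if (acc == d) next
      if (a$resid[acc] == a$resid[d] && a$chain[acc] == a$chain[d]) next
      r <- sqrt(sum((x[acc, ] - x[d, ])^2))
      if (r > r_max) next
      for (h in hs) {
        v1 <- x[h, ] - x[d, ]; v2 <- x[acc, ] - x[d, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang <= theta_max) {
          hits <- hits + 1L
          break
        }
      }
    }
  }
  hits
}

# Random salt-bridge fixture: basic (Lys NZ) and acidic (Asp OD1/OD2)
# residues scattered in a box.
random_sb_fixture <- function(n_basic, n_acidic, box = 14) {
  specs <- list(); xyz <- list(); rid <- 0L
  for (i in seq_len(n_basic)) {
    rid <- rid + 1L
    specs <- c(specs, list(list(name = "NZ", element = "N", resname = "LYS",
                                resid = rid)))
    xyz <- c(xyz, list(runif(3, 0, box)))
  }
  for (i in seq_len(n_acidic)) {
    rid <- rid + 1L
    p <- runif(3, 0, box)
    specs <- c(specs, list(
      list(name = "OD1", element = "O", resname = "ASP", resid = rid),
      list(name = "OD2", element = "O", resname = "ASP", resid = rid)))
    xyz <- c(xyz, list(p, p + c(0.6, 0.8, 0)))
  }
  top <- mk_topology(specs)
  trajectory(top, do.call(rbind, xyz))
}

# Scalar-loop salt-bridge oracle: residue pairs with min N...O <= r_max.
oracle_salt_bridges <- function(traj, r_max = 4.0) {
  x <- frame_coords(traj, 1)
  a <- traj$topology$atoms
  basic_res <- unique(a$resid[a$resname %in% c("LYS", "ARG")])
  acidic_res <- unique(a$resid[a$resname %in% c("ASP", "GLU")])
  basic_atoms <- function(r) which(a$resid == r &
    ((a$resname == "LYS" & a$name == "NZ") |
     (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2"))))
  acidic_atoms <- function(r) which(a$resid == r &
    ((a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
     (a$resname == "GLU" & a$name %in% c("OE1", "OE2"))))
  out <- character(0)
  for (rb in basic_res) {
    for (ra in acidic_res) {
      dmin <- Inf
      for (i in basic_atoms(rb)) {
        for (j in acidic_atoms(ra)) {
          dmin <- min(dmin, sqrt(sum((x[i, ] - x[j, ])^2)))
        }
      }
      if (dmin <= r_max) out <- c(out, paste(rb, ra))
    }
  }
  sort(out)
}

# Fully extended poly-Ala chain (phi = psi = 180): no inter-residue
# contacts anywhere.
build_backbone_fixture <- function(n) {
  bb <- thermotraj:::build_backbone(strrep("A", n), phi = 180, psi = 180)
  thermotraj:::finish_structure(bb$atoms, bb$coords)$trajectory
}

# Rigid-motion transformer for invariance checks.
apply_rigid <- function(traj, axis, theta, shift) {
  rot <- thermotraj:::rotation_about_axis(axis, theta)
  coords <- traj$coords
  for (k in seq_len(n_frames(traj))) {
    coords[k, , ] <- sweep(frame_coords(traj, k) %*% t(rot), 2, shift, "+")
  }
  trajectory(traj$topology, coords, traj$times)
}
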