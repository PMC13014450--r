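# Independent oracle: minimum RMSD over an Euler-angle grid with local
# refinement (translation handled exactly by centroid alignment).
oracle_min_rmsd <- function(mobile, ref) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(ref, 2, colMeans(ref))
  rmsd_at <- function(a, b, g) {
    rz1 <- thermotraj:::rotation_about_axis(c(0, 0, 1), a)
    ry <- thermotraj:::rotation_about_axis(c(0, 1, 0), b)
    rz2 <- thermotraj:::rotation_about_axis(c(0, 0, 1), g)
    r <- rz1 %*% ry %*% rz2
    sqrt(mean(rowSums((p %*% t(r) - q)^2)))
  }
  search <- function(ctr, half, step) {
    best <- c(Inf, ctr)
    for (a in seq(ctr[1] - half, ctr[1] + half, by = step)) {
      for (b in seq(ctr[2] - half, ctr[2] + half, by = step)) {
        for (g in seq(ctr[3] - half, ctr[3] + half, by = step)) {
          v <- rmsd_at(a, b, g)
          if (v < best[1]) best <- c(v, a, b, g)
        }
      }
    }
    best
  }
  b <- search(c(pi, pi / 2, pi), pi, 12 * pi / 180)
  b <- search(b[2:4], 12 * pi / 180, 1 * pi / 180)
  b <- search(b[2:4], 1 * pi / 180, 0.05 * pi / 180)
  b[1]
}

test_that("kabsch recovers identity and rigid motions exactly", {
  set.seed(42)
  x <- matrix(rnorm(15, sd = 3), 5)
  fit <- kabsch(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)

  rot <- thermotraj:::rotation_about_axis(c(0, 0, 1), pi / 2)
  moved <- sweep(x %*% t(rot), 2, c(5, 0, 0), "+")
  fit2 <- kabsch(moved, x)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  # the returned transform maps mobile onto reference
  expect_equal(thermotraj:::apply_superposition(moved, fit2), x,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("kabsch agrees with a rotation-grid search oracle", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 3))
  mobile <- ref
  mobile[4, ] <- mobile[4, ] + c(0.8, -0.5, 0.6)
  expect_lt(abs(kabsch(mobile, ref)$rmsd - oracle_min_rmsd(mobile, ref)),
            1e-3)
})

test_that("kabsch rejects degenerate geometry and bad weights", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(line, line), "collinear")
  x <- matrix(rnorm(12), 4)
  expect_error(kabsch(x, x, weights = rep(0, 4)), "weights")
  expect_error(kabsch(x, x, weights = c(-1, 1, 1, 1)), "weights")
})

test_that("rmsd_series is zero on rigid-body trajectories and at the reference", {
  tp <- build_toy_protein(6, 3)
  tr <- make_rigid_trajectory(tp, 8, seed = 9)
  s <- rmsd_series(tr)
  expect_equal(s$units, "nm")
  expect_true(all(abs(s$values) < 1e-7))

  static <- trajectory(tp$topology,
                       array(rep(tp$coords, each = 4),
                             dim = c(4, nrow(tp$coords), 3)))
  expect_equal(rmsd_series(static)$values, rep(0, 4), tolerance = 1e-12)
  expect_equal(rmsd_series(tr, ref_frame = 5)$values[5], 0, tolerance = 1e-12)
})

test_that("single displaced C-alpha gives RMSD near d/sqrt(n), matching the oracle", {
  hx <- build_ideal_helix(25)
  idx <- select_atoms(hx$topology, "ca")
  n <- length(idx)
  d <- 0.9
  x2 <- hx$coords
  x2[idx[13], ] <- x2[idx[13], ] + c(d, 0, 0)
  coords <- array(NA_real_, dim = c(2, nrow(hx$coords), 3))
  coords[1, , ] <- hx$coords
  coords[2, , ] <- x2
  tr <- trajectory(hx$topology, coords)
  got <- rmsd_series(tr)$values[2] * 10  # back to Angstrom
  expect_lt(abs(got - oracle_min_rmsd(x2[idx, ], hx$coords[idx, ])), 1e-3)
  # the optimal fit absorbs a small part of d/sqrt(n), never exceeds it
  expect_lt(got, d / sqrt(n))
  expect_equal(got, d / sqrt(n), tolerance = 0.05)
})

test_that("radius of gyration matches closed forms and a direct-summation oracle", {
  one <- mk_topology(list(list(name = "CA", element = "C", resname = "ALA",
                               resid = 1)))
  expect_equal(radius_of_gyration_series(
    trajectory(one, matrix(c(1, 2, 3), 1)))$values, 0)

  two <- mk_topology(list(
    list(name = "CA", element = "C", resname = "ALA", resid = 1),
    list(name = "CA", element = "C", resname = "ALA", resid = 2)))
  tr2 <- trajectory(two, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration_series(tr2, mass_weighted = FALSE)$values,
               0.1)  # 1 A in nm

  # unit cube of edge a: every corner is a*sqrt(3)/2 from the center
  a <- 2
  corners <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  cube <- mk_topology(lapply(1:8, function(i) {
    list(name = "CA", element = "C", resname = "ALA", resid = i)
  }))
  trc <- trajectory(cube, corners)
  direct <- sqrt(mean(rowSums(sweep(corners, 2, colMeans(corners))^2))) / 10
  expect_equal(radius_of_gyration_series(trc, mass_weighted = FALSE)$values,
               a * sqrt(3) / 2 / 10)
  expect_equal(radius_of_gyration_series(trc, mass_weighted = FALSE)$values,
               direct)
})

test_that("rmsf handles static, two-frame and error cases", {
  tp <- build_toy_protein(6, 3)
  static <- trajectory(tp$topology,
                       array(rep(tp$coords, each = 3),
                             dim = c(3, nrow(tp$coords), 3)))
  expect_true(all(rmsf_profile(static)$rmsf < 1e-10))

  one_frame <- trajectory(tp$topology, tp$coords)
  expect_error(rmsf_profile(one_frame), "single-frame")

  # two frames, one far atom displaced +/- d about its mean: RMSF = d
  hx <- build_ideal_helix(30)
  idx <- select_atoms(hx$topology, "ca")
  d <- 0.05  # small so the fit perturbation is negligible
  x1 <- hx$coords; x2 <- hx$coords
  x1[idx[15], 1] <- x1[idx[15], 1] + d
  x2[idx[15], 1] <- x2[idx[15], 1] - d
  coords <- array(NA_real_, dim = c(2, nrow(hx$coords), 3))
  coords[1, , ] <- x1; coords[2, , ] <- x2
  prof <- rmsf_profile(trajectory(hx$topology, coords))
  expect_equal(prof$rmsf[15], d / 10, tolerance = 0.05)
})

test_that("native contacts respect the separation rule and match brute force", {
  # two residues at sequence separation 2: no pairs regardless of distance
  close_pair <- mk_topology(list(
    list(name = "CA", element = "C", resname = "ALA", resid = 1),
    list(name = "CA", element = "C", resname = "ALA", resid = 3)))
  trc <- trajectory(close_pair, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(nrow(native_contacts(trc)$pairs), 0L)

  # fully extended chain: no inter-residue contacts within 4.5 A
  ext <- build_backbone_fixture(10)
  expect_equal(nrow(native_contacts(ext)$pairs), 0L)

  # toy fold: pair list equals an O(n^2) brute-force scan
  tp <- build_toy_protein(8, 4)
  tr <- tp$trajectory
  nc <- native_contacts(tr)
  x <- frame_coords(tr, 1)
  a <- tr$topology$atoms
  heavy <- select_atoms(tr$topology, "heavy")
  brute <- character(0)
  for (ii in seq_along(heavy)) {
    for (jj in seq_along(heavy)) {
      i <- heavy[ii]; j <- heavy[jj]
      if (i >= j) next
      if (abs(a$resid[i] - a$resid[j]) <= 3) next
      if (sqrt(sum((x[i, ] - x[j, ])^2)) <= 4.5) brute <- c(brute, paste(i, j))
    }
  }
  expect_gt(nrow(nc$pairs), 0)
  expect_setequal(paste(nc$pairs[, 1], nc$pairs[, 2]), brute)
  expect_true(all(nc$r0 <= nc$cutoff))
})

test_that("q_series reproduces the switching formula exactly", {
  # single contact at r = lambda * r0: the per-contact term is exactly 0.5
  two <- mk_topology(list(
    list(name = "CA", element = "C", resname = "ALA", resid = 1),
    list(name = "CA", element = "C", resname = "ALA", resid = 10)))
  r0 <- 4.0
  contacts <- structure(list(pairs = cbind(1L, 2L), r0 = r0, beta = 5,
                             lambda = 1.8, cutoff = 4.5, min_seq_sep = 3),
                        class = "NativeContactSet")
  tr_mid <- trajectory(two, rbind(c(0, 0, 0), c(1.8 * r0, 0, 0)))
  expect_equal(q_series(tr_mid, contacts)$values, 0.5)

  # toy fold, many frames: matches a direct per-pair summation oracle
  tp <- build_toy_protein(8, 4)
  tr <- make_unfolding_trajectory(tp, seq(1, 1.8, length.out = 20), seed = 3)
  nc <- native_contacts(tp$trajectory)
  q <- q_series(tr, nc)$values
  oracle <- vapply(1:20, function(k) {
    x <- frame_coords(tr, k)
    s <- 0
    for (p in seq_len(nrow(nc$pairs))) {
      r <- sqrt(sum((x[nc$pairs[p, 1], ] - x[nc$pairs[p, 2], ])^2))
      s <- s + 1 / (1 + exp(nc$beta * (r - nc$lambda * nc$r0[p])))
    }
    s / nrow(nc$pairs)
  }, numeric(1))
  expect_equal(q, oracle, tolerance = 1e-12)
  expect_true(all(q > 0 & q < 1))

  # distances scaled x10: Q collapses below 0.01
  big <- trajectory(tp$topology, tp$coords * 10)
  expect_lt(q_series(big, nc)$values, 0.01)
  expect_error(q_series(tr, structure(list(pairs = nc$pairs[0, , drop = FALSE]),
                                      class = "NativeContactSet")), "empty")
})

test_that("descriptors are invariant under global rigid motion", {
  tp <- build_toy_protein(8, 4)
  tr <- make_unfolding_trajectory(tp, c(1, 1.2, 1.5, 1.9), seed = 6)
  nc <- native_contacts(tr)
  moved <- apply_rigid(tr, c(1, 2, 3), 1.1, c(7, -4, 2))

  expect_equal(rmsd_series(moved)$values, rmsd_series(tr)$values,
               tolerance = 1e-8)
  expect_equal(radius_of_gyration_series(moved)$values,
               radius_of_gyration_series(tr)$values, tolerance = 1e-8)
  expect_equal(q_series(moved, nc)$values, q_series(tr, nc)$values,
               tolerance = 1e-8)
  expect_equal(rmsf_profile(moved)$rmsf, rmsf_profile(tr)$rmsf,
               tolerance = 1e-8)
})

test_that("Rg scales linearly and Q decreases under uniform inflation", {
  tp <- build_toy_protein(8, 4)
  tr <- tp$trajectory
  nc <- native_contacts(tr)
  rg0 <- radius_of_gyration_series(tr)$values
  q0 <- q_series(tr, nc)$values
  for (s in c(1.3, 2, 4)) {
    com <- colMeans(tp$coords)
    scaled <- trajectory(tp$topology,
                         sweep(sweep(tp$coords, 2, com) * s, 2, com, "+"))
    expect_equal(radius_of_gyration_series(scaled)$values, rg0 * s,
                 tolerance = 1e-9)
    expect_lt(q_series(scaled, nc)$values, q0)
  }
})
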