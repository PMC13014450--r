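# Three-atom donor/hydrogen/acceptor fixture at prescribed geometry.
dha_fixture <- function(d_da, h_angle_deg = 0) {
  top <- mk_topology(list(
    list(name = "N", element = "N", resname = "ALA", resid = 1),
    list(name = "H", element = "H", resname = "ALA", resid = 1),
    list(name = "O", element = "O", resname = "ALA", resid = 2)))
  a <- h_angle_deg * pi / 180
  xyz <- rbind(c(0, 0, 0), c(cos(a), sin(a), 0), c(d_da, 0, 0))
  trajectory(top, xyz)
}

test_that("hydrogen-bond detection applies both distance and angle cutoffs", {
  hit <- detect_hbonds_frame(dha_fixture(2.9), donor_indices = 1,
                             acceptor_indices = 3)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 2.9)

  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.6), donor_indices = 1,
                                        acceptor_indices = 3)), 0L)
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(2.9, 35), donor_indices = 1,
                                        acceptor_indices = 3)), 0L)
  # boundary: exactly at both cutoffs still counts
  expect_equal(nrow(detect_hbonds_frame(dha_fixture(3.5, 30), donor_indices = 1,
                                        acceptor_indices = 3)), 1L)
})

test_that("donors without hydrogens are skipped with a warning, not an error", {
  top <- mk_topology(list(
    list(name = "N", element = "N", resname = "ALA", resid = 1),
    list(name = "O", element = "O", resname = "ALA", resid = 2)))
  tr <- trajectory(top, rbind(c(0, 0, 0), c(2.9, 0, 0)))
  expect_warning(hit <- detect_hbonds_frame(tr, donor_indices = 1,
                                            acceptor_indices = 2),
                 "no attached hydrogen")
  expect_equal(nrow(hit), 0L)
})

test_that("frame-level hydrogen bonds equal a brute-force oracle on random fixtures", {
  set.seed(31)
  for (rep in 1:8) {
    fx <- random_hb_fixture(n_donor = 8, n_acc = 12)
    don <- which(fx$traj$topology$atoms$name == "N")
    acc <- which(fx$traj$topology$atoms$name == "O")
    got <- detect_hbonds_frame(fx$traj, donor_indices = don,
                               acceptor_indices = acc)
    expect_equal(nrow(got), oracle_hbonds(fx$traj, don, acc))
  }
})

test_that("hbond_series modes behave per contract", {
  hx <- build_ideal_helix(10)
  expect_error(hbond_series(hx$trajectory, "ps"), "water")

  # helix i -> i+4 backbone bonds are found in pp mode
  pp <- hbond_series(hx$trajectory, "pp")
  expect_gte(pp$count[1], 5)
  expect_equal(attr(pp, "mode"), "pp")

  # three engineered protein-water bonds, static: HBps = 3 every frame
  plan <- lapply(c(3, 5, 7), function(r) list(resid = r, atom = "O"))
  wet <- add_water_shell(hx, plan, n_random = 4, seed = 8)
  coords <- array(rep(wet$coords, each = 3), dim = c(3, nrow(wet$coords), 3))
  wtr <- trajectory(wet$topology, coords)
  ps <- hbond_series(wtr, "ps")
  expect_equal(ps$count, rep(3L, 3))
})

test_that("salt-bridge frame detection follows the 4 A minimum N-O rule", {
  mk_pair <- function(d) {
    top <- mk_topology(list(
      list(name = "NZ", element = "N", resname = "LYS", resid = 1),
      list(name = "OD1", element = "O", resname = "ASP", resid = 5)))
    trajectory(top, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  expect_equal(nrow(detect_salt_bridges_frame(mk_pair(3.8))), 1L)
  expect_equal(nrow(detect_salt_bridges_frame(mk_pair(4.1))), 0L)
  expect_equal(detect_salt_bridges_frame(mk_pair(4.0))$basic, "Lys1")

  # monotonicity: lowering r_max never adds a bridge
  set.seed(77)
  fx <- random_sb_fixture(6, 6)
  wide <- detect_salt_bridges_frame(fx, r_max = 4.0)
  narrow <- detect_salt_bridges_frame(fx, r_max = 3.0)
  expect_true(all(paste(narrow$basic, narrow$acidic) %in%
                    paste(wide$basic, wide$acidic)))
})

test_that("salt-bridge detection equals a brute-force oracle on random fixtures", {
  set.seed(19)
  for (rep in 1:8) {
    fx <- random_sb_fixture(7, 7)
    got <- detect_salt_bridges_frame(fx)
    expect_equal(sort(paste(got$basic_resid, got$acidic_resid)),
                 oracle_salt_bridges(fx))
  }
})

test_that("replica frequencies recover engineered presence fractions exactly", {
  tp <- build_toy_protein(8, 4, sequence = "AAKAAAAAAAAADAAA")
  ct <- make_contact_trajectory(tp, 3, 13, p = 0.30, n_frames = 100, seed = 2)
  freq <- salt_bridge_frequencies(replica_set(list(ct), 302))
  expect_equal(nrow(freq), 1L)
  expect_equal(freq$f_mean, 0.300)

  # three replicas engineered at f = 0.2, 0.3, 0.4 average exactly 0.300
  reps <- lapply(seq_along(c(0.2, 0.3, 0.4)), function(i) {
    make_contact_trajectory(tp, 3, 13, p = c(0.2, 0.3, 0.4)[i],
                            n_frames = 100, seed = i)
  })
  freq3 <- salt_bridge_frequencies(replica_set(reps, 302))
  expect_equal(freq3$f_mean, 0.300)
  expect_equal(sort(freq3$f_per_replica[[1]]), c(0.2, 0.3, 0.4))

  # a pair never present is omitted
  ct0 <- make_contact_trajectory(tp, 3, 13, p = 0, n_frames = 50, seed = 4)
  expect_equal(nrow(salt_bridge_frequencies(replica_set(list(ct0), 302))), 0L)
})

test_that("stability classes follow the lower-inclusive boundaries", {
  expect_equal(as.character(classify_stability(0.885)), "high")  # TmY Asp54-Lys104, 450 K
  expect_equal(as.character(classify_stability(c(0.75, 0.74, 0.50, 0.49,
                                                 0.30, 0.29, 0))),
               c("high", "moderate", "moderate", "low", "low", "negligible",
                 "negligible"))
  expect_error(classify_stability(1.2), "\\[0, 1\\]")
})

test_that("formed pairs on the printed tables match the published counts", {
  ecy <- chey_salt_bridge_observations("EcY", 302)
  expect_equal(nrow(formed_pairs(ecy)), 8L)
  tmy <- chey_salt_bridge_observations("TmY", 302)
  expect_equal(nrow(formed_pairs(tmy)), 15L)
  # ordering: descending frequency
  expect_false(is.unsorted(rev(formed_pairs(tmy)$f_mean)))
  # all frequencies below threshold: empty
  none <- data.frame(basic = "Lys1", acidic = "Asp2", f_mean = 0.29)
  expect_equal(nrow(formed_pairs(none)), 0L)
  # a formed pair is never classified negligible
  expect_false(any(classify_stability(formed_pairs(tmy)$f_mean) == "negligible"))
})

test_that("networks reproduce the published motifs for both proteins", {
  ecy_nets <- build_networks(formed_pairs(chey_salt_bridge_observations("EcY", 302)))
  motifs <- vapply(ecy_nets, `[[`, character(1), "motif")
  expect_equal(sum(motifs == "triad"), 1L)
  expect_equal(sum(motifs == "tetrad"), 1L)
  expect_equal(sum(motifs == "dyad"), 3L)
  triad <- ecy_nets[[which(motifs == "triad")]]
  expect_setequal(triad$members, c("Asp12", "Lys109", "Asp57"))
  tetrad <- ecy_nets[[which(motifs == "tetrad")]]
  expect_setequal(tetrad$members, c("Arg22", "Glu35", "Arg18", "Glu37"))

  tmy_nets <- build_networks(formed_pairs(chey_salt_bridge_observations("TmY", 302)))
  tmotifs <- vapply(tmy_nets, `[[`, character(1), "motif")
  expect_equal(sum(tmotifs == "triad"), 2L)
  expect_equal(sum(tmotifs == "tetrad"), 2L)
  expect_equal(sum(tmotifs == "dyad"), 5L)

  expect_equal(build_networks(formed_pairs(chey_salt_bridge_observations("TmY", 302)[0, ])),
               list())
})

test_that("network components partition the formed-pair residues", {
  for (prot in c("TmY", "EcY")) {
    fp <- formed_pairs(chey_salt_bridge_observations(prot, 302))
    nets <- build_networks(fp)
    members <- lapply(nets, `[[`, "members")
    expect_equal(anyDuplicated(unlist(members)), 0L)
    expect_setequal(unlist(members), unique(c(fp$basic, fp$acidic)))
    # edges within each component never exceed what its size admits
    for (n in nets) {
      expect_gte(nrow(n$edges), length(n$members) - 1)
    }
  }
})

test_that("locality classification matches the published intra/inter split", {
  tmy <- chey_salt_bridge_table("TmY")
  emap <- element_map_from_table(tmy)
  expect_equal(classify_locality(c("Lys24", "Asp20"), emap), "intra")
  expect_equal(classify_locality(c("Lys104", "Asp54"), emap), "inter")
  expect_equal(classify_locality(c("Lys24", "Xyz999"), emap), "unassigned")

  loc_tmy <- classify_locality(tmy, emap)
  expect_equal(sum(loc_tmy == "intra"), 5L)   # five intramolecular in TmY
  expect_equal(sum(loc_tmy == "inter"), 10L)  # ten intermolecular

  ecy <- chey_salt_bridge_table("EcY")
  loc_ecy <- classify_locality(ecy, element_map_from_table(ecy))
  expect_equal(sum(loc_ecy == "intra"), 3L)
  expect_equal(sum(loc_ecy == "inter"), 5L)
})

test_that("non-native bridges are flagged at the right temperatures", {
  obs <- function(f) data.frame(basic = c("Lys7", "Arg19"),
                                acidic = c("Glu34", "Asp12"),
                                f_mean = f, stringsAsFactors = FALSE)
  # published mesophilic example: Glu34-Lys7 formed at 400 and 450 K only,
  # Arg19-Asp12 at 450 K only
  by_temp <- list(`302` = obs(c(0.10, 0.05)), `400` = obs(c(0.309, 0.12)),
                  `450` = obs(c(0.337, 0.311)))
  nn <- detect_nonnative_bridges(by_temp, 302)
  expect_equal(nrow(nn), 2L)
  glu34 <- nn[nn$acidic == "Glu34", ]
  expect_equal(sort(glu34$formed_at[[1]]), c(400, 450))
  expect_equal(nn[nn$acidic == "Asp12", ]$formed_at[[1]], 450)

  # a pair formed at every temperature including the reference is not flagged
  always <- list(`302` = obs(c(0.5, 0.1)), `450` = obs(c(0.6, 0.1)))
  expect_equal(nrow(detect_nonnative_bridges(always, 302)), 0L)
  expect_error(detect_nonnative_bridges(always, 328), "not present")
})
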