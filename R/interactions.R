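# Geometric hydrogen-bond and salt-bridge analysis.
#
# Hydrogen bond: donor-acceptor distance <= r_max (3.5 A) and the angle at
# the donor between D->H and D->A <= theta_max (30 deg). The at-donor
# convention reproduces near-linear D-H...A geometry; the literal
# "angle at hydrogen" reading (180 - theta at H) is available via
# `angle_at = "hydrogen"`.
#
# Salt bridge: a Lys/Arg vs Asp/Glu residue pair whose minimum side-chain
# N...O distance is <= r_max (4.0 A, Barlow-Thornton criterion).

#' Hydrogen-bond criteria
#'
#' @param r_max Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param theta_max Angular cutoff in degrees (default 30).
#' @param angle_at `"donor"` (angle between D->H and D->A; default) or
#'   `"hydrogen"` (deviation from linearity at H, i.e. 180 minus the
#'   D-H-A angle).
#' @return List of class `HBondCriteria`.
#' @export
hbond_criteria <- function(r_max = 3.5, theta_max = 30, angle_at = "donor") {
  stopifnot(r_max > 0, theta_max > 0, theta_max < 90)
  angle_at <- match.arg(angle_at, c("donor", "hydrogen"))
  structure(list(r_max = r_max, theta_max = theta_max, angle_at = angle_at),
            class = "HBondCriteria")
}

# Hydrogens covalently attached to each candidate donor, by distance.
attached_hydrogens <- function(x, top, donor_idx, h_max = 1.25) {
  h_idx <- which(toupper(top$atoms$element) == "H")
  if (!length(h_idx) || !length(donor_idx)) {
    return(rep(list(integer(0)), length(donor_idx)))
  }
  d <- cross_dist(x[donor_idx, , drop = FALSE], x[h_idx, , drop = FALSE])
  lapply(seq_along(donor_idx), function(i) h_idx[d[i, ] <= h_max])
}

#' Detect hydrogen bonds in one frame
#'
#' @param traj A [trajectory()] object.
#' @param frame Frame index.
#' @param criteria A [hbond_criteria()] object.
#' @param donor_indices,acceptor_indices Atom indices of candidate donor
#'   heavy atoms (N/O carrying a hydrogen) and acceptors.
#' @param exclude_same_residue Drop intra-residue pairs (default TRUE).
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (Angstrom) and `angle` (degrees). Donors without an
#'   attached hydrogen are skipped with a warning.
#' @export
detect_hbonds_frame <- function(traj, frame = 1L, criteria = hbond_criteria(),
                                donor_indices, acceptor_indices,
                                exclude_same_residue = TRUE) {
  top <- traj$topology
  x <- frame_coords(traj, frame)
  hs <- attached_hydrogens(x, top, donor_indices)
  no_h <- lengths(hs) == 0L
  if (any(no_h)) {
    warning(sum(no_h), " donor atom(s) have no attached hydrogen and were skipped")
  }
  out <- list()
  resid <- top$atoms$resid; chain <- top$atoms$chain
  for (i in seq_along(donor_indices)) {
    if (no_h[i]) next
    d_idx <- donor_indices[i]
    acc <- setdiff(acceptor_indices, d_idx)
    if (exclude_same_residue) {
      acc <- acc[!(resid[acc] == resid[d_idx] & chain[acc] == chain[d_idx])]
    }
    if (!length(acc)) next
    dv <- sweep(x[acc, , drop = FALSE], 2, x[d_idx, ])
    dist_da <- sqrt(rowSums(dv^2))
    near <- which(dist_da <= criteria$r_max)
    for (j in near) {
      a_idx <- acc[j]
      for (h_idx in hs[[i]]) {
        ang <- if (criteria$angle_at == "donor") {
          angle_deg(x[h_idx, ], x[d_idx, ], x[a_idx, ])
        } else {
          180 - angle_deg(x[d_idx, ], x[h_idx, ], x[a_idx, ])
        }
        if (ang <= criteria$theta_max) {
          out[[length(out) + 1L]] <- data.frame(
            donor = d_idx, hydrogen = h_idx, acceptor = a_idx,
            distance = dist_da[j], angle = ang)
          break  # one bond per donor-acceptor pair
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

# Polar heavy atoms (N, O) of a subset that carry at least one hydrogen in
# the given frame.
polar_donors <- function(x, top, subset_idx) {
  cand <- subset_idx[toupper(top$atoms$element[subset_idx]) %in% c("N", "O")]
  hs <- attached_hydrogens(x, top, cand)
  cand[lengths(hs) > 0L]
}

#' Per-frame hydrogen-bond counts
#'
#' `mode = "pp"` counts protein-protein bonds (donors and acceptors both
#' protein polar atoms, intra-residue pairs excluded); `mode = "ps"` counts
#' protein-solvent bonds in either donor/acceptor direction.
#'
#' @param traj A [trajectory()] object.
#' @param mode `"pp"` or `"ps"`.
#' @param criteria A [hbond_criteria()] object.
#' @return Data frame of class `HBondCount` with columns `time_ps`, `count`;
#'   attribute `mode`.
#' @export
hbond_series <- function(traj, mode = c("pp", "ps"), criteria = hbond_criteria()) {
  mode <- match.arg(mode)
  top <- traj$topology
  prot <- select_atoms(top, "protein")
  wat <- select_atoms(top, "water")
  if (mode == "ps" && !length(wat)) {
    stop("mode 'ps' requires water in the topology")
  }
  polar <- function(idx) idx[toupper(top$atoms$element[idx]) %in% c("N", "O")]
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    x <- frame_coords(traj, k)
    if (mode == "pp") {
      don <- polar_donors(x, top, prot)
      nrow(suppressWarnings(
        detect_hbonds_frame(traj, k, criteria, don, polar(prot))))
    } else {
      pw <- nrow(suppressWarnings(
        detect_hbonds_frame(traj, k, criteria, polar_donors(x, top, prot),
                            polar(wat), exclude_same_residue = FALSE)))
      wp <- nrow(suppressWarnings(
        detect_hbonds_frame(traj, k, criteria, polar_donors(x, top, wat),
                            polar(prot), exclude_same_residue = FALSE)))
      pw + wp
    }
  }, numeric(1))
  structure(data.frame(time_ps = traj$times, count = as.integer(counts)),
            mode = mode, class = c("HBondCount", "data.frame"))
}

# ---------------------------------------------------------------------------
# Salt bridges

sb_residue_label <- function(resname, resid) {
  cap <- paste0(substr(resname, 1, 1), tolower(substr(resname, 2, 3)))
  paste0(cap, resid)
}

#' Detect salt bridges in one frame
#'
#' A basic residue (Lys NZ; Arg NE/NH1/NH2) and an acidic residue
#' (Asp OD1/OD2; Glu OE1/OE2) form a salt bridge when their minimum N...O
#' distance is at most `r_max`. Pairs are identified at residue level, so
#' carboxylate-oxygen swaps do not break continuity.
#'
#' @param traj A [trajectory()] object.
#' @param frame Frame index.
#' @param r_max Distance cutoff in Angstrom (default 4.0).
#' @return Data frame with one row per present pair: `basic`, `acidic`
#'   (labels like `"Lys104"`), chain/resid columns and `min_dist`.
#' @export
detect_salt_bridges_frame <- function(traj, frame = 1L, r_max = 4.0) {
  top <- traj$topology
  bi <- select_atoms(top, "basic_sidechain_N")
  ai <- select_atoms(top, "acidic_sidechain_O")
  empty <- data.frame(basic = character(0), acidic = character(0),
                      basic_chain = character(0), basic_resid = integer(0),
                      acidic_chain = character(0), acidic_resid = integer(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE)
  if (!length(bi) || !length(ai)) return(empty)
  x <- frame_coords(traj, frame)
  d <- cross_dist(x[bi, , drop = FALSE], x[ai, , drop = FALSE])
  a <- top$atoms
  bres <- paste(a$chain[bi], a$resid[bi], sep = "\r")
  ares <- paste(a$chain[ai], a$resid[ai], sep = "\r")
  # minimum distance per residue pair
  out <- list()
  for (bu in unique(bres)) {
    for (au in unique(ares)) {
      dm <- min(d[bres == bu, ares == au])
      if (dm <= r_max) {
        i <- bi[match(bu, bres)]; j <- ai[match(au, ares)]
        out[[length(out) + 1L]] <- data.frame(
          basic = sb_residue_label(a$resname[i], a$resid[i]),
          acidic = sb_residue_label(a$resname[j], a$resid[j]),
          basic_chain = a$chain[i], basic_resid = a$resid[i],
          acidic_chain = a$chain[j], acidic_resid = a$resid[j],
          min_dist = dm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Replica-averaged salt-bridge frequencies
#'
#' For every basic x acidic residue pair present in at least one frame of any
#' replica, the per-replica frequency is the fraction of that replica's
#' frames in which the pair is within `r_max`; `f_mean` is the arithmetic
#' mean over replicas. Pairs never present are omitted.
#'
#' @param rset A [replica_set()] object.
#' @param r_max Distance cutoff in Angstrom.
#' @return Data frame of class `SaltBridgeTable` with columns `basic`,
#'   `acidic`, chain/resid columns, `f_mean` and a list column
#'   `f_per_replica`; sorted by descending `f_mean`.
#' @export
salt_bridge_frequencies <- function(rset, r_max = 4.0) {
  stopifnot(inherits(rset, "ReplicaSet"))
  per_rep <- lapply(rset$replicas, function(tr) {
    hits <- lapply(seq_len(n_frames(tr)), function(k) {
      detect_salt_bridges_frame(tr, k, r_max)
    })
    all_hits <- do.call(rbind, hits)
    if (!nrow(all_hits)) return(NULL)
    key <- paste(all_hits$basic, all_hits$acidic)
    cnt <- table(key)
    info <- all_hits[!duplicated(key), , drop = FALSE]
    info$f <- as.numeric(cnt[paste(info$basic, info$acidic)]) / n_frames(tr)
    info
  })
  keys <- unique(unlist(lapply(per_rep, function(d) {
    if (is.null(d)) character(0) else paste(d$basic, d$acidic)
  })))
  if (!length(keys)) {
    out <- data.frame(basic = character(0), acidic = character(0),
                      f_mean = numeric(0))
    class(out) <- c("SaltBridgeTable", "data.frame")
    return(out)
  }
  fmat <- vapply(per_rep, function(d) {
    f <- rep(0, length(keys))
    if (!is.null(d)) f[match(paste(d$basic, d$acidic), keys)] <- d$f
    f
  }, numeric(length(keys)))
  fmat <- matrix(fmat, nrow = length(keys))
  meta <- do.call(rbind, per_rep)
  meta <- meta[match(keys, paste(meta$basic, meta$acidic)), , drop = FALSE]
  out <- data.frame(
    basic = meta$basic, acidic = meta$acidic,
    basic_chain = meta$basic_chain, basic_resid = meta$basic_resid,
    acidic_chain = meta$acidic_chain, acidic_resid = meta$acidic_resid,
    f_mean = rowMeans(fmat), stringsAsFactors = FALSE
  )
  out$f_per_replica <- lapply(seq_len(nrow(fmat)), function(i) fmat[i, ])
  out <- out[order(-out$f_mean, out$basic_resid, out$acidic_resid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SaltBridgeTable", "data.frame")
  out
}

#' Classify salt-bridge stability from its mean frequency
#'
#' Class boundaries are lower-inclusive: `f >= 0.75` high;
#' `0.50 <= f < 0.75` moderate; `0.30 <= f < 0.50` low; `f < 0.30`
#' negligible.
#'
#' @param f_mean Mean formation frequency (or vector), in `[0, 1]`.
#' @return Factor with levels `high`, `moderate`, `low`, `negligible`.
#' @export
classify_stability <- function(f_mean) {
  if (any(f_mean < 0 | f_mean > 1)) stop("frequencies must lie in [0, 1]")
  cls <- ifelse(f_mean >= 0.75, "high",
         ifelse(f_mean >= 0.50, "moderate",
         ifelse(f_mean >= 0.30, "low", "negligible")))
  factor(cls, levels = c("high", "moderate", "low", "negligible"))
}

#' Filter formed salt bridges
#'
#' A pair counts as formed when its replica-mean frequency is at least
#' `threshold` (default 0.30), even if individual replicas fall below it.
#' Output is ordered by descending frequency, ties by residue numbering.
#'
#' @param obs Data frame with an `f_mean` column (e.g. from
#'   [salt_bridge_frequencies()] or a printed-table accessor).
#' @param threshold Formation threshold on `f_mean`.
#' @param f_col Name of the frequency column to filter on.
#' @return The filtered, reordered data frame.
#' @export
formed_pairs <- function(obs, threshold = 0.30, f_col = "f_mean") {
  stopifnot(f_col %in% names(obs))
  keep <- obs[obs[[f_col]] >= threshold, , drop = FALSE]
  o <- order(-keep[[f_col]],
             keep$basic_resid %||% seq_len(nrow(keep)),
             keep$acidic_resid %||% seq_len(nrow(keep)))
  keep <- keep[o, , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Salt-bridge networks from formed pairs
#'
#' Connected components of the residue graph whose edges are the formed
#' pairs. Components are named by size: dyad (2), triad (3), tetrad (4),
#' `"extended network"` beyond that.
#'
#' @param pairs Data frame with columns `basic` and `acidic` (residue
#'   labels), e.g. the output of [formed_pairs()].
#' @return List of `SaltBridgeNetwork` objects, each with `members`
#'   (residue labels), `edges` (2-column matrix) and `motif`; largest
#'   components first.
#' @export
build_networks <- function(pairs) {
  if (!nrow(pairs)) return(list())
  g <- igraph::graph_from_data_frame(pairs[, c("basic", "acidic")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  nets <- lapply(seq_len(comp$no), function(ci) {
    members <- names(comp$membership)[comp$membership == ci]
    in_comp <- pairs$basic %in% members | pairs$acidic %in% members
    edges <- as.matrix(pairs[in_comp, c("basic", "acidic")])
    motif <- switch(as.character(length(members)),
                    "2" = "dyad", "3" = "triad", "4" = "tetrad",
                    "extended network")
    structure(list(members = members, edges = edges, motif = motif),
              class = "SaltBridgeNetwork")
  })
  nets[order(-vapply(nets, function(n) length(n$members), numeric(1)))]
}

#' @export
print.SaltBridgeNetwork <- function(x, ...) {
  cat("<SaltBridgeNetwork> ", x$motif, ": ",
      paste(x$members, collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Classify a salt bridge as intra- or inter-element
#'
#' A pair is `"intra"` when both residues lie within the same named
#' secondary-structure element, `"inter"` when they lie in different
#' elements, and `"unassigned"` when either residue has no element label.
#' (In the source study's vocabulary these are the "intramolecular" and
#' "intermolecular" salt bridges.)
#'
#' @param pair Character vector of two residue labels (e.g.
#'   `c("Lys104", "Asp54")`), or a data frame with `basic`/`acidic` columns
#'   (classified row-wise).
#' @param element_map Named character vector mapping residue labels to
#'   element names (e.g. `c(Asp20 = "alpha1", Lys24 = "alpha1")`).
#' @return Character vector of `"intra"`, `"inter"` or `"unassigned"`.
#' @export
classify_locality <- function(pair, element_map) {
  if (is.data.frame(pair)) {
    return(vapply(seq_len(nrow(pair)), function(i) {
      classify_locality(c(pair$basic[i], pair$acidic[i]), element_map)
    }, character(1)))
  }
  e <- element_map[pair]
  if (anyNA(e)) return("unassigned")
  if (e[1] == e[2]) "intra" else "inter"
}

#' Detect non-native salt bridges across temperatures
#'
#' Flags pairs that are not formed (`f_mean < threshold` or absent) at the
#' reference temperature but formed at one or more higher temperatures.
#'
#' @param obs_by_temp Named list of observation data frames (with `basic`,
#'   `acidic`, `f_mean`), names are temperatures in K.
#' @param reference_temperature Temperature of the folded-state reference.
#' @param threshold Formation threshold.
#' @return Data frame with `basic`, `acidic` and a list column `formed_at`
#'   (the temperatures where the pair is formed).
#' @export
detect_nonnative_bridges <- function(obs_by_temp, reference_temperature,
                                     threshold = 0.30) {
  temps <- as.numeric(names(obs_by_temp))
  if (!reference_temperature %in% temps) {
    stop("reference temperature ", reference_temperature,
         " not present in observations")
  }
  ref <- obs_by_temp[[as.character(reference_temperature)]]
  ref_formed <- paste(ref$basic[ref$f_mean >= threshold],
                      ref$acidic[ref$f_mean >= threshold])
  higher <- temps[temps > reference_temperature]
  hits <- list()
  for (tt in higher) {
    d <- obs_by_temp[[as.character(tt)]]
    f <- d[d$f_mean >= threshold, , drop = FALSE]
    f <- f[!(paste(f$basic, f$acidic) %in% ref_formed), , drop = FALSE]
    if (nrow(f)) hits[[as.character(tt)]] <- cbind(f[, c("basic", "acidic")],
                                                   temperature = tt,
                                                   f_mean = f$f_mean)
  }
  if (!length(hits)) {
    return(data.frame(basic = character(0), acidic = character(0)))
  }
  flat <- do.call(rbind, hits)
  key <- paste(flat$basic, flat$acidic)
  out <- flat[!duplicated(key), c("basic", "acidic"), drop = FALSE]
  out$formed_at <- lapply(unique(key), function(k) flat$temperature[key == k])
  rownames(out) <- NULL
  out
}
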