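# Self-contained DSSP-style secondary-structure assignment.
#
# Backbone hydrogen bonds are scored with the classic electrostatic model
# E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, a bond
# being E < -0.5. From the bond map, n-turns (n = 3, 4, 5) give G/H/I
# helices (two consecutive n-turns form a minimal helix; override priority
# H > G > I), parallel/antiparallel bridge patterns give B, ladders merge to
# E, isolated turn residues get T, the rest C. The three-class collapse maps
# {H, G, I} -> alpha, {E} -> beta, everything else (B, T, C and any bend) ->
# coil.

DSSP_HB_CUTOFF <- -0.5   # kcal/mol
CHAIN_BREAK_CN <- 2.5    # Angstrom, C(i)-N(i+1) beyond this breaks the chain

# Backbone atom indices per protein residue: matrix columns N, CA, C, O, H
# (NA when missing).
backbone_index_table <- function(top) {
  res <- top$residues
  res <- res[res$resname %in% .standard_aa3, , drop = FALSE]
  a <- top$atoms
  find <- function(span, nm) {
    ix <- span[which(a$name[span] == nm)]
    if (length(ix)) ix[1] else NA_integer_
  }
  idx <- t(vapply(seq_len(nrow(res)), function(i) {
    span <- res$first[i]:res$last[i]
    c(N = find(span, "N"), CA = find(span, "CA"), C = find(span, "C"),
      O = find(span, "O"), H = find(span, "H"))
  }, integer(5)))
  list(residues = res, idx = idx)
}

#' Reconstruct backbone amide hydrogens
#'
#' Places H 1.01 Angstrom from N along the external bisector of the
#' C(prev)-N-CA angle (anti to the previous carbonyl oxygen in a planar
#' trans peptide). The first residue of a chain, prolines, and residues
#' following a chain break (C(prev)-N distance > 2.5 Angstrom) get no H.
#' Hydrogens already present in the topology are returned as-is.
#'
#' @param traj A [trajectory()] object.
#' @param frame Frame index.
#' @return Matrix (protein residues x 3) of H positions, `NA` rows where no
#'   H exists; attribute `flagged` marks residues skipped at a chain break.
#' @export
reconstruct_amide_hydrogen <- function(traj, frame = 1L) {
  top <- traj$topology
  bb <- backbone_index_table(top)
  x <- frame_coords(traj, frame)
  nr <- nrow(bb$residues)
  h <- matrix(NA_real_, nr, 3)
  flagged <- logical(nr)
  for (i in seq_len(nr)) {
    if (!is.na(bb$idx[i, "H"])) {
      h[i, ] <- x[bb$idx[i, "H"], ]
      next
    }
    if (bb$residues$resname[i] == "PRO") next
    if (i == 1L || bb$residues$chain[i] != bb$residues$chain[i - 1L]) next
    ni <- bb$idx[i, "N"]; cai <- bb$idx[i, "CA"]; cp <- bb$idx[i - 1L, "C"]
    if (anyNA(c(ni, cai, cp))) next
    if (vnorm(x[ni, ] - x[cp, ]) > CHAIN_BREAK_CN) {
      flagged[i] <- TRUE
      next
    }
    u <- -(unitv(x[cp, ] - x[ni, ]) + unitv(x[cai, ] - x[ni, ]))
    h[i, ] <- x[ni, ] + 1.01 * unitv(u)
  }
  attr(h, "flagged") <- flagged
  h
}

#' Backbone hydrogen-bond energy
#'
#' The electrostatic point-charge model: `E = 0.084 * 332 *
#' (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` in kcal/mol, where C/O belong to the
#' acceptor carbonyl and N/H to the donor amide. A bond exists when
#' `E < -0.5` kcal/mol.
#'
#' @param C,O,N,H Position 3-vectors (Angstrom).
#' @return Energy in kcal/mol.
#' @export
backbone_hbond_energy <- function(C, O, N, H) {
  r <- c(vnorm(O - N), vnorm(C - H), vnorm(O - H), vnorm(C - N))
  if (any(r < 1e-6)) stop("coincident atoms in hydrogen-bond energy evaluation")
  0.084 * 332 * (1 / r[1] + 1 / r[2] - 1 / r[3] - 1 / r[4])
}

# Donor x acceptor bond matrix for one frame: hb[i, j] is TRUE when the NH
# of residue i donates to the CO of residue j.
.dssp_bond_matrix <- function(traj, frame, bb) {
  x <- frame_coords(traj, frame)
  nr <- nrow(bb$residues)
  h <- reconstruct_amide_hydrogen(traj, frame)
  hb <- matrix(FALSE, nr, nr)
  ca <- bb$idx[, "CA"]
  for (i in seq_len(nr)) {        # donor
    if (anyNA(h[i, ]) || is.na(bb$idx[i, "N"])) next
    for (j in seq_len(nr)) {      # acceptor
      # peptide-bonded neighbours are excluded: their covalent geometry
      # trivially satisfies the electrostatic criterion
      if (abs(i - j) < 2L) next
      if (is.na(bb$idx[j, "C"]) || is.na(bb$idx[j, "O"])) next
      if (!is.na(ca[i]) && !is.na(ca[j]) &&
          vnorm(x[ca[i], ] - x[ca[j], ]) > 9) next
      e <- backbone_hbond_energy(x[bb$idx[j, "C"], ], x[bb$idx[j, "O"], ],
                                 x[bb$idx[i, "N"], ], h[i, ])
      hb[i, j] <- e < DSSP_HB_CUTOFF
    }
  }
  hb
}

.dssp_frame <- function(traj, frame, bb) {
  nr <- nrow(bb$residues)
  if (nr < 3L) return(rep("C", nr))
  hb <- .dssp_bond_matrix(traj, frame, bb)
  same_chain <- function(i, j) bb$residues$chain[i] == bb$residues$chain[j]

  turn <- function(n) {
    t <- logical(nr)
    for (i in seq_len(nr - n)) {
      t[i] <- hb[i + n, i] && same_chain(i, i + n)
    }
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  codes <- rep("C", nr)

  # turns first (lowest override priority)
  for (n in c(3, 4, 5)) {
    tn <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(n)]]
    for (i in which(tn)) {
      span <- (i + 1):(i + n - 1)
      codes[span[span <= nr]] <- "T"
    }
  }

  # bridges / strands
  bridge <- logical(nr)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nr - 1)) {
      if (abs(i - j) <= 2L) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[j, i] && hb[i, j]) ||
        (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) bridge[i] <- TRUE
    }
  }
  r <- rle(bridge)
  pos <- cumsum(c(1, r$lengths))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    span <- pos[k]:(pos[k + 1] - 1)
    codes[span] <- if (length(span) >= 2L) "E" else "B"
  }

  # helices, ascending priority I < G < H
  minimal_helix <- function(tn, n, code) {
    for (i in seq_len(nr)) {
      if (i >= 2L && tn[i - 1] && tn[i]) {
        codes[i:(i + n - 1)] <<- ifelse(
          codes[i:(i + n - 1)] %in% .helix_overridable(code),
          code, codes[i:(i + n - 1)])
      }
    }
  }
  .helix_overridable <- function(code) {
    switch(code,
           I = c("C", "T"),
           G = c("C", "T", "I"),
           H = c("C", "T", "I", "G", "B", "E"))
  }
  minimal_helix(t5, 5, "I")
  minimal_helix(t3, 3, "G")
  minimal_helix(t4, 4, "H")

  codes
}

#' Map DSSP codes to the three-class scheme
#'
#' `{H, G, I}` -> `"alpha"`, `{E}` -> `"beta"`, everything else (`B`, `T`,
#' `C`, bends) -> `"coil"`. The mapping is total.
#'
#' @param codes Character vector/matrix of DSSP codes.
#' @return Same shape, values `"alpha"`, `"beta"`, `"coil"`.
#' @export
ss_class <- function(codes) {
  out <- ifelse(codes %in% c("H", "G", "I"), "alpha",
         ifelse(codes == "E", "beta", "coil"))
  if (is.matrix(codes)) dim(out) <- dim(codes)
  out
}

#' DSSP-style secondary-structure assignment
#'
#' @param traj A [trajectory()] object with complete backbones (amide H
#'   reconstructed where absent).
#' @param frames Frame indices (default all).
#' @return Object of class `SSAssignment`: `codes` and `classes` matrices
#'   (frames x protein residues) plus the residue table.
#' @export
assign_dssp_lite <- function(traj, frames = NULL) {
  bb <- backbone_index_table(traj$topology)
  frames <- frames %||% seq_len(n_frames(traj))
  codes <- t(vapply(frames, function(k) .dssp_frame(traj, k, bb),
                    character(nrow(bb$residues))))
  if (nrow(bb$residues) == 1L) codes <- matrix(codes, ncol = 1L)
  structure(list(codes = codes, classes = ss_class(codes),
                 residues = bb$residues, frames = frames,
                 times = traj$times[frames]),
            class = "SSAssignment")
}

#' @export
print.SSAssignment <- function(x, ...) {
  cat("<SSAssignment> ", nrow(x$codes), " frame(s) x ", ncol(x$codes),
      " residues\n", sep = "")
  invisible(x)
}

#' Per-frame three-class secondary-structure content
#'
#' @param traj A [trajectory()] object, or an `SSAssignment` already
#'   computed.
#' @return Data frame of class `SSContentSeries` with columns `time_ps`,
#'   `alpha`, `beta`, `coil` (percentages summing to 100 per frame).
#' @export
ss_content_series <- function(traj) {
  ssa <- if (inherits(traj, "SSAssignment")) traj else assign_dssp_lite(traj)
  cl <- ssa$classes
  nr <- ncol(cl)
  pct <- function(what) 100 * rowSums(cl == what) / nr
  out <- data.frame(time_ps = ssa$times, alpha = pct("alpha"),
                    beta = pct("beta"), coil = pct("coil"))
  class(out) <- c("SSContentSeries", "data.frame")
  out
}

#' Census of a secondary-structure assignment
#'
#' Counts residues per DSSP category (alpha-helix H, 3_10-helix G, pi-helix
#' I, strand E, coil = everything else) with percentages of the total; used
#' for crystal-structure composition accounting.
#'
#' @param codes Character vector of per-residue DSSP codes.
#' @return Data frame with columns `category`, `n`, `percent`.
#' @export
ss_census <- function(codes) {
  n <- length(codes)
  cat_of <- function(code) sum(codes == code)
  counts <- c(alpha_helix = cat_of("H"), three10_helix = cat_of("G"),
              pi_helix = cat_of("I"), beta_strand = cat_of("E"))
  counts <- c(counts, coil = n - sum(counts))
  data.frame(category = names(counts), n = as.integer(counts),
             percent = round(100 * counts / n, 2), row.names = NULL)
}

#' Per-element persistence across a trajectory
#'
#' For each named secondary-structure element (a residue range with an
#' expected class), the persistence is the fraction of frames in which at
#' least `threshold` of the element's residues hold that class.
#'
#' @param ssa An `SSAssignment` (or a trajectory, assigned on the fly).
#' @param elements Data frame with columns `name`, `chain`, `start`, `end`,
#'   `class` (`"alpha"` or `"beta"`); see [chey_ss_elements()].
#' @param threshold Minimum fraction of element residues in class.
#' @return Data frame with columns `name`, `n_residues`, `persistence`.
#' @export
element_persistence <- function(ssa, elements, threshold = 0.5) {
  if (!inherits(ssa, "SSAssignment")) ssa <- assign_dssp_lite(ssa)
  stopifnot(all(c("name", "chain", "start", "end", "class") %in% names(elements)))
  res <- ssa$residues
  out <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    cols <- which(res$chain == e$chain & res$resid >= e$start &
                    res$resid <= e$end)
    if (!length(cols)) stop("element ", e$name, " covers no residues")
    frac <- rowMeans(ssa$classes[, cols, drop = FALSE] == e$class)
    data.frame(name = e$name, n_residues = length(cols),
               persistence = mean(frac >= threshold))
  })
  do.call(rbind, out)
}

#' Ile/Leu/Val composition per secondary-structure class
#'
#' Counts the ILV (hydrophobic-core) residues within each class and reports
#' the percentage of that class's residues they represent.
#'
#' @param sequence One-letter sequence as a single string or character
#'   vector, one residue per class label.
#' @param classes Per-residue class labels (`"alpha"`, `"beta"`, `"coil"`).
#' @return Data frame with columns `class`, `n_residues`, `n_ilv`, `percent`.
#' @export
ilv_composition <- function(sequence, classes) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  stopifnot(length(sequence) == length(classes))
  ilv <- toupper(sequence) %in% c("I", "L", "V")
  out <- lapply(c("alpha", "beta", "coil"), function(cl) {
    in_cl <- classes == cl
    n <- sum(in_cl); k <- sum(ilv & in_cl)
    data.frame(class = cl, n_residues = n, n_ilv = k,
               percent = if (n > 0) round(100 * k / n, 1) else 0)
  })
  do.call(rbind, out)
}
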