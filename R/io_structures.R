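#' Build a topology from an atom table
#'
#' A `Topology` is the static description of a molecular system: one row per
#' atom plus a derived residue table and per-chain one-letter sequences.
#' Coordinates live in the companion [Trajectory] container.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, and optionally `mass` and `hetero`.
#' @return An object of class `Topology` with elements `atoms` (data.frame),
#'   `residues` (one row per residue with the atom index span) and `sequence`
#'   (named character vector of per-chain one-letter sequences).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("serial", "name", "resname", "resid", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  atoms$water <- atoms$resname %in% .water_resnames
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  atoms$hetero <- atoms$hetero & !atoms$water & !(atoms$resname %in% .standard_aa3)
  if (any(atoms$mass <= 0)) stop("all atom masses must be positive")

  key <- paste(atoms$chain, atoms$resid, sep = "\r")
  idx <- which(!duplicated(key))
  residues <- data.frame(
    chain = atoms$chain[idx],
    resid = atoms$resid[idx],
    resname = atoms$resname[idx],
    first = idx,
    last = c(idx[-1] - 1L, nrow(atoms)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(residues$chain, residues$resid))) {
    stop("(chain, resid) pairs must be unique and contiguous in the atom table")
  }

  prot <- residues[residues$resname %in% .standard_aa3, , drop = FALSE]
  sequence <- vapply(split(prot, prot$chain), function(d) {
    paste(.aa3_to_1[d$resname], collapse = "")
  }, character(1))

  structure(list(atoms = atoms, residues = residues, sequence = sequence),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("<Topology> ", nrow(x$atoms), " atoms, ", nrow(x$residues), " residues, ",
      length(x$sequence), " chain(s)\n", sep = "")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Build a trajectory container
#'
#' @param topology A [topology()] object.
#' @param coords Numeric array `F x N x 3` of coordinates in Angstrom, or an
#'   `N x 3` matrix for a single frame.
#' @param times Frame times in ps (default 0, 100, 200, ... following the
#'   100-ps save convention); must be strictly increasing.
#' @param box Optional per-frame list of 3x3 lattice-vector matrices (Angstrom).
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, box = NULL) {
  stopifnot(inherits(topology, "Topology"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("coordinate array has ", dim(coords)[2], " atoms but the topology has ",
         n_atoms(topology))
  }
  nf <- dim(coords)[1]
  if (nf < 1L) stop("a trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(times)) times <- seq(0, by = 100, length.out = nf)
  if (length(times) != nf || any(diff(times) <= 0)) {
    stop("times must have one strictly increasing value per frame")
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("<Trajectory> ", n_frames(x), " frame(s) x ", n_atoms(x$topology),
      " atoms\n", sep = "")
  invisible(x)
}

#' @rdname trajectory
#' @param traj A `Trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj A `Trajectory`.
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Group replica trajectories simulated at one temperature
#'
#' @param replicas List of [trajectory()] objects sharing one topology.
#' @param temperature Simulation temperature in K.
#' @param label Protein/system name.
#' @return An object of class `ReplicaSet`.
#' @export
replica_set <- function(replicas, temperature, label = "protein") {
  if (!length(replicas)) stop("a replica set needs at least one trajectory")
  stopifnot(all(vapply(replicas, inherits, logical(1), "Trajectory")))
  a0 <- replicas[[1]]$topology$atoms
  same <- vapply(replicas, function(tr) {
    a <- tr$topology$atoms
    nrow(a) == nrow(a0) && all(a$name == a0$name) && all(a$resid == a0$resid) &&
      all(a$chain == a0$chain) && all(a$resname == a0$resname)
  }, logical(1))
  if (!all(same)) stop("all replicas must share an identical topology")
  structure(list(temperature = temperature, replicas = replicas, label = label),
            class = "ReplicaSet")
}

# ---------------------------------------------------------------------------
# PDB I/O (multi-model PDB is the reference trajectory dialect)

#' Read a (multi-model) PDB file
#'
#' Parses ATOM/HETATM records, one trajectory frame per MODEL block (a single
#' frame when no MODEL records are present). Alternate locations are resolved
#' to the highest occupancy, ties broken by first listed. Waters (HOH/SOL/...)
#' are flagged on the topology.
#'
#' @param path Path to a PDB file.
#' @return A list with elements `topology` and `trajectory`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  frame_id <- cumsum(model_starts)
  if (!any(model_starts)) frame_id <- rep(1L, length(lines))
  frame_id[frame_id == 0L] <- 1L

  al <- lines[is_atom]
  if (!length(al)) stop("empty structure: no ATOM/HETATM records in ", path)
  af <- frame_id[is_atom]

  num_field <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad)) {
      stop("malformed ", what, " field in PDB line ", lineno[bad[1]], ": '",
           s[bad[1]], "'")
    }
    v
  }
  lineno <- which(is_atom)
  fields <- list(
    serial = trimws(substr(al, 7, 11)),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resid = trimws(substr(al, 23, 26)),
    x = substr(al, 31, 38), y = substr(al, 39, 46), z = substr(al, 47, 54),
    occ = substr(al, 55, 60),
    element = trimws(substr(al, 77, 78)),
    hetero = substr(al, 1, 6) == "HETATM"
  )
  x <- num_field(fields$x, "x coordinate", lineno)
  y <- num_field(fields$y, "y coordinate", lineno)
  z <- num_field(fields$z, "z coordinate", lineno)
  occ <- suppressWarnings(as.numeric(fields$occ))
  occ[is.na(occ)] <- 1

  d <- data.frame(
    serial = suppressWarnings(as.integer(fields$serial)),
    name = fields$name, altloc = fields$altloc, resname = fields$resname,
    chain = fields$chain, resid = suppressWarnings(as.integer(fields$resid)),
    x = x, y = y, z = z, occ = occ, element = fields$element,
    hetero = fields$hetero, frame = af, stringsAsFactors = FALSE
  )
  if (anyNA(d$resid)) stop("malformed residue number field in PDB file ", path)

  # altloc resolution within the first frame's atom list: keep, per
  # (chain, resid, name), the record with the highest occupancy (first wins
  # ties). The same atom subset is applied to every frame.
  f1 <- d[d$frame == min(d$frame), , drop = FALSE]
  akey <- paste(f1$chain, f1$resid, f1$name, sep = "\r")
  keep1 <- unlist(lapply(split(seq_len(nrow(f1)), factor(akey, levels = unique(akey))),
                         function(ix) ix[which.max(f1$occ[ix])]),
                  use.names = FALSE)
  keep1 <- sort(keep1)
  f1 <- f1[keep1, , drop = FALSE]

  frames <- sort(unique(d$frame))
  nf <- length(frames)
  na <- nrow(f1)
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (k in seq_along(frames)) {
    fk <- d[d$frame == frames[k], , drop = FALSE]
    kk <- paste(fk$chain, fk$resid, fk$name, sep = "\r")
    sel <- unlist(lapply(split(seq_len(nrow(fk)), factor(kk, levels = unique(kk))),
                         function(ix) ix[which.max(fk$occ[ix])]),
                  use.names = FALSE)
    fk <- fk[sort(sel), , drop = FALSE]
    if (nrow(fk) != na) {
      stop("MODEL block ", k, " has ", nrow(fk), " atoms; expected ", na)
    }
    coords[k, , ] <- cbind(fk$x, fk$y, fk$z)
  }

  atoms <- data.frame(
    serial = ifelse(is.na(f1$serial), seq_len(na), f1$serial),
    name = f1$name,
    element = ifelse(nzchar(f1$element), f1$element, guess_element(f1$name)),
    resname = f1$resname, resid = f1$resid, chain = f1$chain,
    hetero = f1$hetero, stringsAsFactors = FALSE
  )
  top <- topology(atoms)
  list(topology = top, trajectory = trajectory(top, coords))
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' One MODEL block per frame; a single-frame trajectory is written without
#' MODEL/ENDMDL records. Coordinates are written at PDB precision (3 decimals).
#'
#' @param traj A [trajectory()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  if (!all(is.finite(traj$coords))) stop("coordinates must be finite")
  at <- traj$topology$atoms
  nf <- n_frames(traj)

  fmt_name <- function(nm) {
    # standard PDB convention: names of <4 chars start in column 14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  rectype <- ifelse(at$hetero | at$water, "HETATM", "ATOM  ")
  body <- character(0)
  for (k in seq_len(nf)) {
    xyz <- frame_coords(traj, k)
    lines <- sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rectype, at$serial %% 100000L, fmt_name(at$name), at$resname,
                     at$chain, at$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
                     1, 0, toupper(at$element))
    if (nf > 1L) {
      body <- c(body, sprintf("MODEL     %4d", k), lines, "ENDMDL")
    } else {
      body <- c(body, lines)
    }
  }
  writeLines(c(body, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection

.selector_tokens <- c("ca", "backbone", "heavy", "protein", "water",
                      "basic_sidechain_N", "acidic_sidechain_O", "all")

#' Select atoms by a small selector grammar
#'
#' The grammar is a named set optionally narrowed by a residue range:
#' `"<set>"` or `"<set> resid <a>:<b>"`. Sets: `ca`, `backbone` (N/CA/C/O),
#' `heavy` (protein non-hydrogen), `protein`, `water`, `basic_sidechain_N`
#' (Lys NZ; Arg NE/NH1/NH2), `acidic_sidechain_O` (Asp OD1/OD2; Glu OE1/OE2),
#' `all`.
#'
#' @param top A [topology()] object.
#' @param selector Selector string.
#' @return Sorted integer vector of atom indices.
#' @export
select_atoms <- function(top, selector) {
  stopifnot(inherits(top, "Topology"))
  parts <- strsplit(trimws(selector), "\\s+")[[1]]
  if (!length(parts)) stop("empty selector")
  set <- parts[1]
  if (!set %in% .selector_tokens) {
    stop("unknown selector '", set, "'; valid selectors: ",
         paste(.selector_tokens, collapse = ", "))
  }
  a <- top$atoms
  is_protein <- a$resname %in% .standard_aa3
  keep <- switch(set,
    all = rep(TRUE, nrow(a)),
    protein = is_protein,
    water = a$water,
    ca = is_protein & a$name == "CA",
    backbone = is_protein & a$name %in% c("N", "CA", "C", "O"),
    heavy = is_protein & toupper(a$element) != "H",
    basic_sidechain_N = (a$resname == "LYS" & a$name == "NZ") |
      (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2")),
    acidic_sidechain_O = (a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
      (a$resname == "GLU" & a$name %in% c("OE1", "OE2"))
  )
  if (length(parts) > 1L) {
    if (length(parts) != 3L || parts[2] != "resid") {
      stop("selector filter must be of the form 'resid <a>:<b>'")
    }
    rng <- suppressWarnings(as.integer(strsplit(parts[3], "[:-]")[[1]]))
    if (anyNA(rng)) stop("malformed residue range '", parts[3], "'")
    if (length(rng) == 1L) rng <- c(rng, rng)
    keep <- keep & a$resid >= rng[1] & a$resid <= rng[2]
  }
  sort(which(keep))
}
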