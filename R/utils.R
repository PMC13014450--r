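# Internal geometry and chemistry helpers. Length unit is Angstrom throughout
# the internals; user-facing descriptor series convert to nm.

ANGSTROM_PER_NM <- 10

# Standard atomic masses (amu) for the elements that occur in protein + water
# systems at this package's scale.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305
)

.standard_aa3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.aa3_to_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

.water_resnames <- c("HOH", "SOL", "WAT", "TIP3", "SPC")

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  m[is.na(m)] <- 12.011  # unknown elements fall back to carbon mass
  unname(m)
}

# Guess the element from a PDB atom name when columns 77-78 are blank.
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9' ]", "", nm)
    if (nzchar(nm)) substr(nm, 1L, 1L) else "C"
  }, character(1), USE.NAMES = FALSE)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Angle at vertex b of the triangle a-b-c, in degrees.
angle_deg <- function(a, b, c) {
  u <- unitv(a - b)
  w <- unitv(c - b)
  acos(max(-1, min(1, sum(u * w)))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for an angle (radians) about a unit axis.
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Place atom D given positions A-B-C, the B-C-D angle (deg), the A-B-C-D
# dihedral (deg) and the C-D bond length: standard internal-coordinate (NeRF)
# construction used by the synthetic builders.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# All pairwise distances between two coordinate blocks (rows are atoms).
cross_dist <- function(x, y) {
  sx <- rowSums(x^2)
  sy <- rowSums(y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
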