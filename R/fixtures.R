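# Synthetic PDB fixtures with exactly controlled geometry.
#
# Residues are built from idealised internal coordinates (bond lengths,
# bond angles, torsions; sidechains extended at chi = 180 unless a branch
# forces otherwise) so that every analysis in the package can be exercised
# without downloading experimental structures. These are geometric unit
# scaffolds, not realistic conformers.

# z-matrix rows: name, element, ref atoms a/b/c, bond (A), angle, torsion
# (degrees). The backbone seed N/CA/C is placed explicitly.
residue_zmat <- function(restype) {
  z <- function(name, el, a, b, c, bond, angle, torsion) {
    list(name = name, el = el, a = a, b = b, c = c,
         bond = bond, angle = angle, torsion = torsion)
  }
  bb <- list(z("O", "O", "N", "CA", "C", 1.231, 120.5, 180))
  cb <- z("CB", "C", "C", "N", "CA", 1.530, 110.5, -122)
  side <- switch(
    restype,
    GLY = list(),
    ALA = list(cb),
    VAL = list(
      cb,
      z("CG1", "C", "N", "CA", "CB", 1.521, 110.5, 180),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, -60)
    ),
    LEU = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.530, 116.3, 180),
      z("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, 180),
      z("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, -60)
    ),
    ILE = list(
      cb,
      z("CG1", "C", "N", "CA", "CB", 1.530, 110.4, 180),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, -60),
      z("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, 180)
    ),
    SER = list(
      cb,
      z("OG", "O", "N", "CA", "CB", 1.417, 111.1, 180)
    ),
    THR = list(
      cb,
      z("OG1", "O", "N", "CA", "CB", 1.433, 109.6, 180),
      z("CG2", "C", "N", "CA", "CB", 1.521, 110.5, -60)
    ),
    CYS = list(
      cb,
      z("SG", "S", "N", "CA", "CB", 1.808, 114.4, 180)
    ),
    MET = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 180),
      z("SD", "S", "CA", "CB", "CG", 1.803, 112.7, 180),
      z("CE", "C", "CB", "CG", "SD", 1.791, 100.9, 180)
    ),
    ASP = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.516, 112.6, 180),
      z("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, 0),
      z("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, 180)
    ),
    ASN = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.516, 112.6, 180),
      z("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, 0),
      z("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 180)
    ),
    GLU = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 180),
      z("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 180),
      z("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, 0),
      z("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, 180)
    ),
    GLN = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 180),
      z("CD", "C", "CA", "CB", "CG", 1.516, 112.6, 180),
      z("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, 0),
      z("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, 180)
    ),
    LYS = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 180),
      z("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 180),
      z("CE", "C", "CB", "CG", "CD", 1.508, 111.3, 180),
      z("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, 180)
    ),
    ARG = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.520, 114.1, 180),
      z("CD", "C", "CA", "CB", "CG", 1.520, 111.3, 180),
      z("NE", "N", "CB", "CG", "CD", 1.461, 112.0, 180),
      z("CZ", "C", "CG", "CD", "NE", 1.329, 124.2, 180),
      z("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, 0),
      z("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, 180)
    ),
    HIS = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.497, 113.8, 180),
      z("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, 90),
      z("CD2", "C", "CA", "CB", "CG", 1.356, 131.1, -90),
      z("CE1", "C", "CB", "CG", "ND1", 1.321, 109.2, 180),
      z("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, 180)
    ),
    PHE = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.502, 113.8, 180),
      z("CD1", "C", "CA", "CB", "CG", 1.391, 120.8, 90),
      z("CD2", "C", "CA", "CB", "CG", 1.391, 120.8, -90),
      z("CE1", "C", "CB", "CG", "CD1", 1.391, 120.0, 180),
      z("CE2", "C", "CB", "CG", "CD2", 1.391, 120.0, 180),
      z("CZ", "C", "CG", "CD1", "CE1", 1.391, 120.0, 0),
      z("HZ_DEL", "X", "", "", "", 0, 0, 0)
    ),
    TYR = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.502, 113.8, 180),
      z("CD1", "C", "CA", "CB", "CG", 1.391, 120.8, 90),
      z("CD2", "C", "CA", "CB", "CG", 1.391, 120.8, -90),
      z("CE1", "C", "CB", "CG", "CD1", 1.391, 120.0, 180),
      z("CE2", "C", "CB", "CG", "CD2", 1.391, 120.0, 180),
      z("CZ", "C", "CG", "CD1", "CE1", 1.391, 120.0, 0),
      z("OH", "O", "CD1", "CE1", "CZ", 1.377, 120.0, 180)
    ),
    TRP = list(
      cb,
      z("CG", "C", "N", "CA", "CB", 1.498, 113.6, 180),
      z("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, 90),
      z("CD2", "C", "CA", "CB", "CG", 1.433, 126.8, -90),
      z("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, 180),
      z("CE2", "C", "CB", "CG", "CD2", 1.409, 107.2, 180),
      z("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, 0),
      z("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, 180),
      z("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.6, 180),
      z("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)
    ),
    abort(paste0("unsupported residue type: ", restype))
  )
  side <- side[vapply(side, function(e) e$el != "X", logical(1))]
  c(bb, side)
}

#' Build an idealised single residue as an atom tibble
#'
#' The backbone nitrogen sits at the origin and the sidechain is extended
#' along +x. Heavy atoms only; hydrogens are added by [protonate()].
#'
#' @param restype 3-letter residue code (standard amino acids except PRO).
#' @param resno Residue number assigned to all atoms.
#' @return A tibble with columns `name`, `element`, `resid`, `resno`,
#'   `x`, `y`, `z`.
#' @export
residue_template <- function(restype, resno = 1L) {
  restype <- toupper(restype)
  zmat <- residue_zmat(restype)
  coords <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0),
    C = c(1.458, 0, 0) + 1.525 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  )
  for (e in zmat) {
    coords[[e$name]] <- place_dihedral(
      coords[[e$a]], coords[[e$b]], coords[[e$c]], e$bond, e$angle, e$torsion
    )
  }
  xyz <- do.call(rbind, coords)
  tibble(
    name = names(coords),
    element = c("N", "C", "C", vapply(zmat, function(e) e$el, character(1))),
    resid = restype, resno = as.integer(resno),
    x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3])
  )
}

#' Generate a two-residue PDB fixture at an exact closest-atom separation
#'
#' Two idealised residues are placed with their sidechains facing each
#' other; the second residue is then translated along x until the minimum
#' heavy-atom distance between the two residues equals `separation`
#' exactly (to the precision representable in PDB coordinate columns).
#'
#' @param restype_a,restype_b 3-letter residue codes.
#' @param separation Target closest heavy-atom distance in Angstrom (> 0).
#' @param approach_angle Angle (degrees) between the tip-to-tip vector
#'   and the first residue's sidechain axis. The default 0 gives a
#'   head-on approach; an oblique angle (e.g. 70) places the partner
#'   off-axis, which is the geometry a rotatable hydroxyl needs to form
#'   a hydrogen bond.
#' @return PDB text (single string).
#' @export
#' @examples
#' txt <- make_pair("LYS", "GLU", 3.5)
#' s <- read_structure(text = txt)
make_pair <- function(restype_a, restype_b, separation, approach_angle = 0) {
  stopifnot(is.numeric(separation), separation > 0)
  a <- residue_template(restype_a, resno = 1L)
  b <- residue_template(restype_b, resno = 2L)

  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  # face the second residue's sidechain back along the approach direction
  u <- c(cos(deg2rad(approach_angle)), sin(deg2rad(approach_angle)), 0)
  pb <- pb %*% t(rotation_matrix(c(0, 0, 1), 180 + approach_angle))

  tip_a <- which.max(pa[, 1])
  tip_b <- which.min(pb %*% u)
  shift0 <- pa[tip_a, ] + separation * u - pb[tip_b, ]
  pb <- sweep(pb, 2, shift0, "+")

  min_dist <- function(extra) {
    pbx <- sweep(pb, 2, extra * u, "+")
    min(sqrt(outer(pa[, 1], pbx[, 1], "-")^2 +
               outer(pa[, 2], pbx[, 2], "-")^2 +
               outer(pa[, 3], pbx[, 3], "-")^2))
  }
  # aligned tips give min <= separation; shifting further along the
  # approach direction only increases the minimum distance
  if (min_dist(0) < separation - 1e-9) {
    extra <- stats::uniroot(function(s) min_dist(s) - separation,
                            lower = 0, upper = 50, tol = 1e-12)$root
    pb <- sweep(pb, 2, extra * u, "+")
  }
  b$x <- pb[, 1]; b$y <- pb[, 2]; b$z <- pb[, 3]

  atoms <- bind_rows(a, b)
  s <- as_structure(atoms, source_id = paste0(restype_a, "-", restype_b))
  write_structure(s)
}

#' Decorate fixture PDB text with degenerate records for parser tests
#'
#' @param pdb_text PDB text from [make_pair()] or [write_structure()].
#' @param decorations Character vector among `"altloc"` (the first
#'   sidechain atom is duplicated as altloc A, occupancy 0.60, and a
#'   shifted altloc B, occupancy 0.40), `"multimodel"` (the file becomes
#'   two MODELs, the second translated by +10 A in z) and `"hetatm"`
#'   (a HETATM water is appended).
#' @return Decorated PDB text.
#' @export
make_decorated <- function(pdb_text, decorations) {
  decorations <- match.arg(decorations, c("altloc", "multimodel", "hetatm"),
                           several.ok = TRUE)
  s <- read_structure(text = pdb_text)
  atoms <- as_tibble(s)
  atoms$occ <- 1

  if ("altloc" %in% decorations) {
    i <- which(!(atoms$name %in% c("N", "CA", "C", "O")))[1]
    alt_a <- atoms[i, ]; alt_a$altloc <- "A"; alt_a$occ <- 0.60
    alt_b <- atoms[i, ]; alt_b$altloc <- "B"; alt_b$occ <- 0.40
    alt_b$x <- alt_b$x + 0.5
    atoms <- bind_rows(
      atoms[seq_len(i - 1), ], alt_a, alt_b,
      if (i < nrow(atoms)) atoms[seq(i + 1, nrow(atoms)), ]
    )
    atoms$serial <- seq_len(nrow(atoms))
  }

  lines <- pdb_atom_lines(atoms)

  if ("hetatm" %in% decorations) {
    wat <- tibble(
      serial = max(atoms$serial) + 1L, name = "O", altloc = "",
      resid = "HOH", chain = "A", resno = max(atoms$resno) + 1L,
      insert = "", x = 30, y = 30, z = 30, element = "O", het = TRUE,
      occ = 1
    )
    lines <- c(lines, pdb_atom_lines(wat))
  }

  if ("multimodel" %in% decorations) {
    atoms2 <- atoms
    atoms2$z <- atoms2$z + 10
    lines <- c("MODEL        1", lines, "ENDMDL",
               "MODEL        2", pdb_atom_lines(atoms2), "ENDMDL")
  }

  paste(c(lines, "END"), collapse = "\n")
}
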