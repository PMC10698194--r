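# ---- element / atom-type parameter tables -----------------------------------

# van der Waals radii (Angstrom), Bondi-style values for the heavy atoms that
# occur in peptide/receptor models plus hydrogen.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Van der Waals radius of an element
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
atom_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  bad <- is.na(r)
  if (any(bad)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  }
  unname(r)
}

# Minimal declared partial-charge table for the simplified score function.
# Keyed on atom name class, not on a force field: backbone amide N is a weak
# positive donor, carbonyl C positive, carbonyl/hydroxyl O negative.
.atom_charge_table <- c(
  N = 0.35, C = 0.45, O = -0.50, CA = 0.00, CB = 0.00, S = -0.10
)

#' Partial charge for an atom
#'
#' Minimal per-atom-type charge table used by [total_energy()]. Backbone N/C/O
#' get amide-like charges; apolar carbons and sulfur are (near) neutral;
#' side-chain pseudo-atoms carry the charge from the residue parameter table.
#'
#' @param name atom name (e.g. "N", "CA", "C", "O", "SG").
#' @param element element symbol.
#' @return numeric charge (elementary charge units).
#' @export
atom_charge <- function(name, element) {
  q <- .atom_charge_table[name]
  q[is.na(q)] <- 0
  # generic fallbacks by element for non-backbone polar atoms
  miss <- !(name %in% names(.atom_charge_table))
  q[miss & toupper(element) == "O"] <- -0.40
  q[miss & toupper(element) == "N"] <- 0.30
  q[miss & toupper(element) == "S"] <- -0.10
  unname(q)
}

.backbone_names <- c("N", "CA", "C", "O")

# ---- structure3d container --------------------------------------------------

#' Construct a 3D structure object
#'
#' A light container for a (possibly multi-model) molecular structure: a flat
#' atom table, one coordinate matrix per model, and named residue-set
#' annotations (e.g. "ECL2", "ECL3", "orthosteric"). All models share the atom
#' topology; residue identity follows author (PDB) numbering, 1-based.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `name`,
#'   `element`, `x`, `y`, `z` (model-1 coordinates; `insert` optional).
#' @param models list of n-atom x 3 coordinate matrices; defaults to the single
#'   model given by the atom table.
#' @param annotations named list; each element a character vector of residue
#'   keys as produced by [residue_key()].
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, models = NULL, annotations = list()) {
  need <- c("chain", "resno", "resname", "name", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (is.null(models)) models <- list(as.matrix(atoms[, c("x", "y", "z")]))
  models <- lapply(models, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L || nrow(m) != nrow(atoms))
      stop("every model must be an n-atom x 3 coordinate matrix")
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    m
  })
  if (any(!is.finite(models[[1]]))) stop("non-finite coordinates in model 1")
  atoms[, c("x", "y", "z")] <- models[[1]]
  keys <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  for (nm in names(annotations)) {
    unknown <- setdiff(annotations[[nm]], keys)
    if (length(unknown))
      stop("annotation '", nm, "' references absent residues: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(atoms = atoms, models = models, annotations = annotations),
            class = "structure3d")
}

#' Residue key from chain / residue number / insertion code
#'
#' @param chain,resno,insert vectors (recycled).
#' @return character keys like `"A:57"`.
#' @export
residue_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(residue_key(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      "residues,", length(x$models), "model(s)\n")
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Number of models (frames) in a structure
#' @param x a `structure3d`.
#' @return integer.
#' @export
n_models <- function(x) length(x$models)

#' Coordinates of one model
#' @param x a `structure3d`.
#' @param model model index (1-based).
#' @return n x 3 matrix.
#' @export
model_coords <- function(x, model = 1L) {
  if (model < 1L || model > length(x$models)) stop("model index out of range")
  x$models[[model]]
}

#' Atoms belonging to an annotated residue set
#' @param x a `structure3d`.
#' @param annotation annotation name.
#' @return logical vector over atoms.
#' @export
annotation_atoms <- function(x, annotation) {
  if (!annotation %in% names(x$annotations))
    stop("missing annotation: ", annotation)
  keys <- residue_key(x$atoms$chain, x$atoms$resno, x$atoms$insert)
  keys %in% x$annotations[[annotation]]
}

# ---- PDB I/O (bio3d-backed) -------------------------------------------------

.water_names <- c("HOH", "WAT", "DOD", "H2O")
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Read a PDB file or text into a structure3d
#'
#' Wraps `bio3d::read.pdb()`. ATOM/HETATM/MODEL records are supported; altloc
#' conflicts are resolved per policy, waters are dropped by default, hydrogens
#' are retained. Amino-acid residues missing any of N/CA/C raise a structural
#' error naming the residue. Coordinate fields are pre-validated so a malformed
#' record raises a parse error naming the offending line.
#'
#' @param input path to a PDB file, or PDB text (single string with newlines or
#'   a character vector of lines).
#' @param model_policy `"all"` keeps every MODEL as an ensemble frame;
#'   `"first"` keeps model 1 only.
#' @param altloc_policy `"first"` (default) keeps blank/first altloc only;
#'   `"all"` keeps everything.
#' @param drop_waters drop water residues (default TRUE).
#' @return a [structure3d()].
#' @export
read_pdb <- function(input, model_policy = c("all", "first"),
                     altloc_policy = c("first", "all"), drop_waters = TRUE) {
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  if (length(input) > 1L || grepl("\n", input[1]) || grepl("^ATOM|^HETATM|^MODEL", input[1])) {
    lines <- if (length(input) > 1L) input else strsplit(input, "\n", fixed = TRUE)[[1]]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  } else {
    path <- input
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
  }
  is_coord <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(is_coord)) {
    ln <- lines[i]
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field in PDB line ", i, ": ", trimws(ln))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                         rm.alt = (altloc_policy == "first"))
  at <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  keep <- rep(TRUE, nrow(at))
  if (drop_waters) keep <- keep & !(at$resid %in% .water_names)
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(t(outer(which(keep), c(0, 1, 2), function(i, o) 3 * (i - 1) + 1 + o)))
  xyz <- xyz[, cols, drop = FALSE]
  nm <- if (model_policy == "first") 1L else nrow(xyz)
  models <- lapply(seq_len(nm), function(m)
    matrix(xyz[m, ], ncol = 3, byrow = TRUE))
  chain <- ifelse(is.na(at$chain), "", at$chain)
  insert <- ifelse(is.na(at$insert), "", at$insert)
  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   substr(trimws(at$elety), 1, 1), at$elesy)))
  atoms <- data.frame(chain = chain, resno = at$resno, insert = insert,
                      resname = at$resid, name = trimws(at$elety),
                      element = element,
                      x = models[[1]][, 1], y = models[[1]][, 2], z = models[[1]][, 3],
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  # structural validation: amino-acid residues need N, CA, C
  keyv <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  aa <- atoms$resname %in% c(.aa3, "CYY")
  if (any(aa)) {
    bad <- vapply(split(atoms$name[aa], keyv[aa]), function(nms)
      !all(c("N", "CA", "C") %in% nms), logical(1))
    if (any(bad))
      stop("amino-acid residue(s) missing backbone N/CA/C: ",
           paste(names(bad)[bad], collapse = ", "))
  }
  structure3d(atoms, models)
}

#' Write a structure3d as a (multi-model) PDB file
#'
#' Wraps `bio3d::write.pdb()`. Multi-model structures are written with
#' MODEL/ENDMDL records; coordinates round-trip to PDB format precision
#' (1e-3 Angstrom).
#'
#' @param x a [structure3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  at <- x$atoms
  xyz <- do.call(rbind, lapply(x$models, function(m) as.vector(t(m))))
  het <- if ("het" %in% names(at)) at$het else !(at$resname %in% .aa3)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = ifelse(at$chain == "", " ", at$chain),
                   insert = ifelse(at$insert == "", "", at$insert),
                   elesy = at$element)
  invisible(path)
}

# ---- geometric primitives ---------------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

#' Dihedral angle of four points
#'
#' Signed torsion in degrees in (-180, 180], IUPAC sign convention (positive =
#' clockwise rotation of p4 relative to p1 when looking from p2 towards p3).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b1) < 1e-9 || .vnorm(b2) < 1e-9 || .vnorm(b3) < 1e-9)
    stop("consecutive points coincide; dihedral undefined")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9)
    stop("colinear points; dihedral undefined")
  m1 <- .cross3(n1, b2 / .vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle of three points, degrees
#' @param p1,p2,p3 numeric 3-vectors; vertex at `p2`.
#' @return angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Place a fourth atom by internal coordinates (NeRF construction)
#'
#' Given positions of atoms a-b-c, returns the position of atom d with bond
#' length |c-d|, bond angle b-c-d, and torsion a-b-c-d.
#'
#' @param a,b,c numeric 3-vectors.
#' @param length bond length c-d, Angstrom.
#' @param angle bond angle b-c-d, degrees.
#' @param torsion dihedral a-b-c-d, degrees.
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / .vnorm(n)
  m <- .cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rigid transform container
#'
#' @param rotation 3x3 proper rotation matrix (det = +1).
#' @param translation numeric 3-vector (Angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xform a [rigid_transform()].
#' @param coords n x 3 matrix (or 3-vector).
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(xform, coords) {
  v <- is.null(dim(coords))
  m <- if (v) matrix(coords, ncol = 3) else as.matrix(coords)
  out <- m %*% t(xform$rotation)
  out <- sweep(out, 2, xform$translation, "+")
  if (v) as.numeric(out) else out
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `moving` onto `fixed`, reflections
#' excluded (proper rotation only). Warns when the point set is degenerate
#' (colinear) but still returns the least-squares transform.
#'
#' @param moving,fixed N x 3 coordinate matrices, N >= 3, matching rows.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd` (Angstrom)
#'   of the superposed sets.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3 || ncol(fixed) != 3)
    stop("coordinate sets must be matching N x 3 matrices")
  if (nrow(moving) < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(crossprod(A, B))
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    warning("degenerate (colinear) point set; superposition is not unique")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cf - as.numeric(R %*% cm)
  xform <- rigid_transform(R, t_vec)
  moved <- apply_transform(xform, moving)
  list(transform = xform, rmsd = rmsd_coords(moved, fixed))
}

#' RMSD between two coordinate sets (no superposition)
#' @param a,b N x 3 matrices.
#' @return root-mean-square deviation, Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in shape")
  sqrt(mean(rowSums((a - b)^2)))
}
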