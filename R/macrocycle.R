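# Macrocycle backbone sampling, thioether ring closure, torsion-bin strings,
# backbone H-bond fingerprints and exact-key clustering.

# ideal backbone geometry (Angstrom / degrees)
.geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  cb_sg = 1.810, n_h = 1.010,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_c_ca_cb = 110.5, ang_ca_cb_sg = 114.0,
  chir_improper = 122.6,      # N-C-CA-CB improper, +L / -D
  # bromoacetyl bridge unit: N(term)-C(=O)-CH2 ... S
  n_cl = 1.33, cl_cm = 1.52, cl_ol = 1.23,
  ang_ca_n_cl = 121.5, ang_n_cl_cm = 116.0, ang_n_cl_ol = 123.0
)

#' Thioether bridge geometry targets and tolerances
#'
#' Closure targets for the Cys side-chain-to-N-terminus thioether: the
#' S-gamma to bridge-CH2 bond and the C-S-C angle at sulfur, with declared
#' tolerances. The CH2-C(=O) and C(=O)-N(term) bonds are built at ideal
#' geometry and listed for reference.
#'
#' @param cys_index ring position of the bridging Cys (defaults to the last
#'   ring residue).
#' @param bond_sg_ch2,bond_ch2_c,bond_c_n target bond lengths, Angstrom.
#' @param angle_csc target C-S-C angle, degrees.
#' @param tol_bond,tol_angle closure tolerances (Angstrom / degrees).
#' @return object of class `thioether_bridge`.
#' @export
thioether_bridge <- function(cys_index = NULL, bond_sg_ch2 = 1.81,
                             bond_ch2_c = 1.52, bond_c_n = 1.33,
                             angle_csc = 100, tol_bond = 0.2, tol_angle = 15) {
  if (tol_bond <= 0 || tol_angle <= 0) stop("closure tolerances must be > 0")
  structure(list(cys_index = cys_index, bond_sg_ch2 = bond_sg_ch2,
                 bond_ch2_c = bond_ch2_c, bond_c_n = bond_c_n,
                 angle_csc = angle_csc, tol_bond = tol_bond,
                 tol_angle = tol_angle),
            class = "thioether_bridge")
}

# run expr with a private, seeded RNG stream; global RNG state is restored
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

# Ramachandran prior: 3-component Gaussian mixture over (phi, psi), mirrored
# for D residues; omega trans 180 +/- 5 with 5% cis.
.rama_centers <- matrix(c(-63, -41, -120, 130, 60, 40), ncol = 2, byrow = TRUE)
.rama_weights <- c(0.45, 0.45, 0.10)
.rama_sigma <- 20

.sample_phi_psi <- function(n, chirality) {
  comp <- sample.int(3, n, replace = TRUE, prob = .rama_weights)
  phi <- .rama_centers[comp, 1] + stats::rnorm(n, 0, .rama_sigma)
  psi <- .rama_centers[comp, 2] + stats::rnorm(n, 0, .rama_sigma)
  mir <- chirality == "D"
  phi[mir] <- -phi[mir]; psi[mir] <- -psi[mir]
  cbind(.wrap180(phi), .wrap180(psi))
}

.sample_omega <- function(n, p_cis = 0.05) {
  cis <- stats::runif(n) < p_cis
  .wrap180(ifelse(cis, 0, 180) + stats::rnorm(n, 0, 5))
}

# ---- backbone construction --------------------------------------------------

# Build full-atom (N,H,CA,C,O,CB[,SG]) macrocycle coordinates from torsions,
# plus the bromoacetyl bridge unit (CL carbonyl C, OL, CM methylene) on the
# N-terminus. Returns an atom data.frame with res_idx 0 for the bridge.
.build_backbone_atoms <- function(res, phi0 = 180, chi1 = -60) {
  n <- nrow(res)
  g <- .geom
  pos <- list()  # named "i.NAME"
  put <- function(i, nm, p) pos[[paste0(i, ".", nm)]] <<- p
  get_ <- function(i, nm) pos[[paste0(i, ".", nm)]]
  # residue 1 seed frame
  put(1, "N", c(0, 0, 0))
  put(1, "CA", c(g$n_ca, 0, 0))
  sa <- (180 - g$ang_n_ca_c) * pi / 180
  put(1, "C", get_(1, "CA") + g$ca_c * c(cos(sa), sin(sa), 0))
  for (i in seq_len(n)) {
    if (i > 1) {
      put(i, "N", place_atom(get_(i - 1, "N"), get_(i - 1, "CA"), get_(i - 1, "C"),
                             g$c_n, g$ang_ca_c_n, res$psi[i - 1]))
      put(i, "CA", place_atom(get_(i - 1, "CA"), get_(i - 1, "C"), get_(i, "N"),
                              g$n_ca, g$ang_c_n_ca, res$omega[i]))
      put(i, "C", place_atom(get_(i - 1, "C"), get_(i, "N"), get_(i, "CA"),
                             g$ca_c, g$ang_n_ca_c, res$phi[i]))
    }
    put(i, "O", place_atom(get_(i, "N"), get_(i, "CA"), get_(i, "C"),
                           g$c_o, g$ang_ca_c_o, .wrap180(res$psi[i] + 180)))
    sgn <- if (res$chirality[i] == "D") -1 else 1
    put(i, "CB", place_atom(get_(i, "N"), get_(i, "C"), get_(i, "CA"),
                            g$ca_cb, g$ang_c_ca_cb, sgn * g$chir_improper))
  }
  # bridge unit off residue-1 N (bromoacetyl-derived CH2-C(=O)-N)
  put(0, "CL", place_atom(get_(1, "C"), get_(1, "CA"), get_(1, "N"),
                          g$n_cl, g$ang_ca_n_cl, phi0))
  put(0, "CM", place_atom(get_(1, "CA"), get_(1, "N"), get_(0, "CL"),
                          g$cl_cm, g$ang_n_cl_cm, 180))
  put(0, "OL", place_atom(get_(1, "CA"), get_(1, "N"), get_(0, "CL"),
                          g$cl_ol, g$ang_n_cl_ol, 0))
  # amide hydrogens: H on N, anti to the carbonyl C preceding it
  for (i in seq_len(n)) {
    cprev <- if (i == 1) get_(0, "CL") else get_(i - 1, "C")
    put(i, "H", place_atom(get_(i, "CA"), cprev, get_(i, "N"),
                           g$n_h, 119, 180))
  }
  # Cys S-gamma on the last ring residue
  put(n, "SG", place_atom(get_(n, "N"), get_(n, "CA"), get_(n, "CB"),
                          g$cb_sg, g$ang_ca_cb_sg, chi1))
  ord <- c("0.CL", "0.OL", "0.CM",
           unlist(lapply(seq_len(n), function(i) {
             nm <- c("N", "H", "CA", "C", "O", "CB")
             if (i == n) nm <- c(nm, "SG")
             paste0(i, ".", nm)
           })))
  xyz <- do.call(rbind, pos[ord])
  parts <- strsplit(ord, ".", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 2)
  data.frame(res_idx = as.integer(vapply(parts, `[`, "", 1)),
             name = nm,
             element = ifelse(nm == "SG", "S",
                       ifelse(nm == "H", "H",
                       ifelse(nm %in% c("N"), "N",
                       ifelse(nm %in% c("O", "OL"), "O", "C")))),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.atom_xyz <- function(atoms, res_idx, name) {
  i <- which(atoms$res_idx == res_idx & atoms$name == name)
  if (!length(i)) stop("atom not found: residue ", res_idx, " ", name)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

#' Measure thioether closure residuals from coordinates
#'
#' Re-measures, from coordinates alone, the S-gamma to bridge-CH2 distance and
#' the C-S-C (CB to S-gamma to CH2) angle of a macrocycle, and compares them to
#' the bridge targets.
#'
#' @param backbone a [peptide_backbone()].
#' @return list with `bond` (Angstrom), `angle` (degrees), `bond_dev`,
#'   `angle_dev` (absolute deviations from target) and `ok` (within tolerance).
#' @export
closure_residuals <- function(backbone) {
  at <- backbone$atoms
  n <- backbone$ring_size
  sg <- .atom_xyz(at, n, "SG"); cm <- .atom_xyz(at, 0, "CM")
  cb <- .atom_xyz(at, n, "CB")
  br <- backbone$bridge
  d <- sqrt(sum((sg - cm)^2))
  a <- bond_angle(cb, sg, cm)
  list(bond = d, angle = a,
       bond_dev = abs(d - br$bond_sg_ch2),
       angle_dev = abs(a - br$angle_csc),
       ok = abs(d - br$bond_sg_ch2) <= br$tol_bond &&
            abs(a - br$angle_csc) <= br$tol_angle)
}

#' Construct a macrocyclic peptide backbone from torsions
#'
#' Builds ideal-geometry backbone coordinates (N, H, CA, C, O, CB per residue,
#' S-gamma on the closing Cys, and the bromoacetyl-derived CH2-C(=O) bridge
#' unit on the N-terminus) from per-residue phi/psi/omega. The returned object
#' is "open" until [close_ring()] succeeds (or the torsions already satisfy
#' the bridge geometry).
#'
#' @param phi,psi,omega numeric vectors, degrees, one value per ring residue.
#' @param chirality character vector, "L"/"D" per residue.
#' @param name3 three-letter codes per residue; defaults to ALA with a closing
#'   CYS.
#' @param bridge a [thioether_bridge()].
#' @param phi0 bridge-unit orientation torsion (C1-CA1-N1-CL), degrees.
#' @param chi1 Cys chi1 torsion, degrees.
#' @param provenance optional list (seed, sample index) carried through.
#' @return object of class `peptide_backbone`.
#' @export
peptide_backbone <- function(phi, psi, omega, chirality = NULL, name3 = NULL,
                             bridge = thioether_bridge(), phi0 = 180,
                             chi1 = -60, provenance = list()) {
  n <- length(phi)
  if (length(psi) != n || length(omega) != n)
    stop("phi, psi, omega must have equal length")
  if (is.null(chirality)) chirality <- rep("L", n)
  if (is.null(name3)) name3 <- c(rep("ALA", n - 1), "CYS")
  res <- data.frame(idx = seq_len(n), name3 = name3, chirality = chirality,
                    phi = .wrap180(phi), psi = .wrap180(psi),
                    omega = .wrap180(omega), stringsAsFactors = FALSE)
  atoms <- .build_backbone_atoms(res, phi0 = phi0, chi1 = chi1)
  bridge$cys_index <- n
  bb <- structure(list(ring_size = n, residues = res, atoms = atoms,
                       bridge = bridge, provenance = provenance,
                       closure = NULL),
                  class = "peptide_backbone")
  cr <- closure_residuals(bb)
  bb$closure <- list(success = cr$ok, bond = cr$bond, angle = cr$angle,
                     iterations = 0L)
  bb
}

#' @export
print.peptide_backbone <- function(x, ...) {
  cl <- x$closure
  cat(sprintf("peptide_backbone: %d-mer thioether macrocycle [%s], closure %s (S-C %.2f A, C-S-C %.1f deg, %d CCD iter)\n",
              x$ring_size, paste(x$residues$chirality, collapse = ""),
              if (isTRUE(cl$success)) "closed" else "OPEN",
              cl$bond, cl$angle, cl$iterations))
  invisible(x)
}

# rotate points about an axis (Rodrigues), theta in degrees
.rotate_about <- function(pts, origin, axis, theta) {
  u <- axis / .vnorm(axis)
  th <- theta * pi / 180
  v <- sweep(pts, 2, origin)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(v %*% t(R), 2, origin, "+")
}

# indices of atoms downstream of a torsion (the set that moves when it turns)
.downstream_idx <- function(atoms, n, kind, i) {
  ri <- atoms$res_idx
  nm <- atoms$name
  if (kind == "phi") {
    # axis N_i -> CA_i: moves C,O,CB(,SG) of residue i and all later residues
    which((ri == i & nm %in% c("C", "O", "CB", "SG")) | (ri > i))
  } else if (kind == "psi") {
    # axis CA_i -> C_i: moves O_i and all later residues
    which((ri == i & nm == "O") | (ri > i))
  } else { # chi1 of the closing Cys: axis CA_n -> CB_n moves SG
    which(ri == n & nm == "SG")
  }
}

.closure_objective <- function(sg, cb, cm, bridge) {
  d <- sqrt(sum((sg - cm)^2))
  a <- bond_angle(cb, sg, cm)
  ((d - bridge$bond_sg_ch2) / bridge$tol_bond)^2 +
    ((a - bridge$angle_csc) / bridge$tol_angle)^2
}

# closure objective for a vector of candidate rotations about one torsion;
# Rodrigues applied in closed form to the (at most two) objective atoms
.ccd_objectives <- function(thetas, sg0, cb0, cm, origin, axis,
                            sg_moves, cb_moves, bridge) {
  u <- axis / .vnorm(axis)
  th <- thetas * pi / 180
  ct <- cos(th); st <- sin(th)
  rot_pt <- function(p) {
    v <- p - origin
    w <- .cross3(u, v)
    k <- sum(u * v)
    # 3 x m matrix of rotated positions
    origin + outer(v, ct) + outer(w, st) + outer(u, k * (1 - ct))
  }
  sg <- if (sg_moves) rot_pt(sg0) else matrix(sg0, 3, length(th))
  cb <- if (cb_moves) rot_pt(cb0) else matrix(cb0, 3, length(th))
  dv <- sg - cm
  d <- sqrt(colSums(dv * dv))
  u1 <- cb - sg; u2 <- -dv
  cosang <- colSums(u1 * u2) / (sqrt(colSums(u1 * u1)) * d)
  a <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  ((d - bridge$bond_sg_ch2) / bridge$tol_bond)^2 +
    ((a - bridge$angle_csc) / bridge$tol_angle)^2
}

#' Close a thioether macrocycle by cyclic coordinate descent
#'
#' Adjusts the phi/psi torsions of the last three ring residues (plus the Cys
#' chi1) by cyclic coordinate descent until the thioether bridge residuals
#' (S-gamma to CH2 bond, C-S-C angle) fall within tolerance, or `max_iter`
#' sweeps are exhausted. Failure is a value: the returned backbone carries
#' `closure$success = FALSE` with the residuals. A backbone already satisfying
#' the bridge geometry is returned unchanged with 0 iterations.
#'
#' @param backbone a [peptide_backbone()].
#' @param max_iter maximum CCD sweeps (default 200).
#' @return the backbone with updated coordinates, re-measured torsions and a
#'   `closure` record (`success`, `bond`, `angle`, `iterations`).
#' @export
close_ring <- function(backbone, max_iter = 200L) {
  cr <- closure_residuals(backbone)
  if (cr$ok) {
    backbone$closure <- list(success = TRUE, bond = cr$bond, angle = cr$angle,
                             iterations = 0L)
    return(backbone)
  }
  at <- backbone$atoms
  n <- backbone$ring_size
  xyz <- as.matrix(at[, c("x", "y", "z")])
  idx_of <- function(ri, nm) which(at$res_idx == ri & at$name == nm)
  cm <- xyz[idx_of(0, "CM"), ]
  i_sg <- idx_of(n, "SG"); i_cb <- idx_of(n, "CB")
  tors <- list()
  for (i in seq(max(1, n - 2), n)) {
    tors[[length(tors) + 1]] <- list(kind = "phi", i = i,
      a1 = idx_of(i, "N"), a2 = idx_of(i, "CA"))
    tors[[length(tors) + 1]] <- list(kind = "psi", i = i,
      a1 = idx_of(i, "CA"), a2 = idx_of(i, "C"))
  }
  tors[[length(tors) + 1]] <- list(kind = "chi1", i = n,
    a1 = idx_of(n, "CA"), a2 = idx_of(n, "CB"))
  grid <- seq(-175, 180, by = 5)
  iter <- 0L
  ok <- FALSE
  obj_prev <- Inf
  while (iter < max_iter && !ok) {
    iter <- iter + 1L
    for (tv in tors) {
      origin <- xyz[tv$a1, ]; axis <- xyz[tv$a2, ] - origin
      move <- .downstream_idx(at, n, tv$kind, tv$i)
      sg_moves <- i_sg %in% move; cb_moves <- i_cb %in% move
      if (!sg_moves && !cb_moves) next
      f <- function(th) .ccd_objectives(th, xyz[i_sg, ], xyz[i_cb, ], cm,
                                        origin, axis, sg_moves, cb_moves,
                                        backbone$bridge)
      vals <- f(grid)
      best <- grid[which.min(vals)]
      fine <- seq(best - 4.75, best + 4.75, by = 0.25)
      fvals <- f(fine)
      theta <- if (min(fvals) < min(vals)) fine[which.min(fvals)] else best
      if (abs(theta) > 1e-9) {
        xyz[move, ] <- .rotate_about(xyz[move, , drop = FALSE], origin, axis, theta)
      }
    }
    sg <- xyz[i_sg, ]; cb <- xyz[i_cb, ]
    d <- sqrt(sum((sg - cm)^2)); a <- bond_angle(cb, sg, cm)
    ok <- abs(d - backbone$bridge$bond_sg_ch2) <= backbone$bridge$tol_bond &&
      abs(a - backbone$bridge$angle_csc) <= backbone$bridge$tol_angle
    obj <- .closure_objective(sg, cb, cm, backbone$bridge)
    if (!ok && obj_prev - obj < 1e-8) break  # stalled in a local minimum
    obj_prev <- obj
  }
  at[, c("x", "y", "z")] <- xyz
  backbone$atoms <- at
  backbone$residues <- .measure_torsions(backbone)
  cr <- closure_residuals(backbone)
  backbone$closure <- list(success = cr$ok, bond = cr$bond, angle = cr$angle,
                           iterations = iter)
  backbone
}

# re-measure phi/psi/omega from coordinates (bridge atoms close the ring at
# the N-terminal side; psi_n is taken through the carbonyl O convention)
.measure_torsions <- function(backbone) {
  at <- backbone$atoms
  n <- backbone$ring_size
  res <- backbone$residues
  gx <- function(i, nm) .atom_xyz(at, i, nm)
  for (i in seq_len(n)) {
    cprev <- if (i == 1) gx(0, "CL") else gx(i - 1, "C")
    res$phi[i] <- dihedral(cprev, gx(i, "N"), gx(i, "CA"), gx(i, "C"))
    if (i < n) {
      res$psi[i] <- dihedral(gx(i, "N"), gx(i, "CA"), gx(i, "C"), gx(i + 1, "N"))
    } else {
      res$psi[i] <- .wrap180(
        dihedral(gx(i, "N"), gx(i, "CA"), gx(i, "C"), gx(i, "O")) + 180)
    }
    caprev <- if (i == 1) gx(0, "CM") else gx(i - 1, "CA")
    res$omega[i] <- dihedral(caprev, cprev, gx(i, "N"), gx(i, "CA"))
  }
  res
}

#' Sample a library of closed thioether macrocycle backbones
#'
#' Draws per-residue (phi, psi) from a declared Ramachandran prior (Gaussian
#' mixture at the alpha/beta/left-handed basins, sign-mirrored for D
#' residues), omega trans with a small cis fraction, builds ideal-geometry
#' coordinates, and closes the thioether ring by [close_ring()]. Only
#' backbones whose re-measured closure residuals pass the bridge tolerances
#' are returned. Deterministic under `seed`.
#'
#' @param ring_size number of ring residues, 4 to 12 (the design campaign uses
#'   5 and 6).
#' @param n_samples number of closed backbones requested.
#' @param seed integer RNG seed.
#' @param p_d probability a residue is sampled as D (default 0.5).
#' @param p_cis cis-omega fraction (default 0.05).
#' @param bridge a [thioether_bridge()].
#' @param max_attempts sampling budget before giving up (default
#'   `50 * n_samples`).
#' @return list of [peptide_backbone()] objects, length `n_samples`.
#' @export
sample_backbones <- function(ring_size, n_samples, seed, p_d = 0.5,
                             p_cis = 0.05, bridge = thioether_bridge(),
                             max_attempts = 50L * n_samples) {
  if (ring_size < 4 || ring_size > 12)
    stop("ring_size must be between 4 and 12 (got ", ring_size, ")")
  if (n_samples < 1) stop("n_samples must be >= 1")
  .with_seed(seed, {
    out <- vector("list", n_samples)
    got <- 0L
    attempt <- 0L
    while (got < n_samples && attempt < max_attempts) {
      attempt <- attempt + 1L
      chir <- ifelse(stats::runif(ring_size) < p_d, "D", "L")
      pp <- .sample_phi_psi(ring_size, chir)
      om <- .sample_omega(ring_size, p_cis)
      bb <- peptide_backbone(pp[, 1], pp[, 2], om, chirality = chir,
                             bridge = bridge,
                             phi0 = stats::runif(1, -180, 180),
                             chi1 = sample(c(-60, 60, 180), 1),
                             provenance = list(seed = seed, attempt = attempt))
      bb <- close_ring(bb)
      if (isTRUE(bb$closure$success)) {
        got <- got + 1L
        bb$provenance$index <- got
        out[[got]] <- bb
      }
    }
    if (got == 0L)
      stop("sampling exhausted: 0 closures in ", attempt,
           " attempts (ring_size=", ring_size, ")")
    if (got < n_samples)
      warning("sampling budget reached: returning ", got, " of ",
              n_samples, " requested backbones")
    out[seq_len(got)]
  })
}

# ---- torsion bins -----------------------------------------------------------

#' Assign a torsion-bin label to one (phi, psi, omega) triple
#'
#' Five-letter torsion alphabet partitioning the backbone torus: `O` whenever
#' |omega| < 90 (cis-like), otherwise `A` (phi < 0, psi in [-75, 50)), `B`
#' (phi < 0, psi outside), `G` (phi >= 0, psi in [-100, 100)), `E` (phi >= 0,
#' psi outside). phi = 180 is treated as -180.
#'
#' @param phi,psi,omega degrees (vectors allowed).
#' @return character vector of bin labels.
#' @export
torsion_bin <- function(phi, psi, omega) {
  phi <- .wrap180(phi); psi <- .wrap180(psi); omega <- .wrap180(omega)
  if (any(is.na(c(phi, psi, omega)))) stop("undefined torsion")
  phi <- ifelse(phi == 180, -180, phi)
  ifelse(abs(omega) < 90, "O",
    ifelse(phi < 0,
      ifelse(psi >= -75 & psi < 50, "A", "B"),
      ifelse(psi >= -100 & psi < 100, "G", "E")))
}

#' Torsion-bin string of a macrocycle backbone
#'
#' @param backbone a [peptide_backbone()].
#' @return single string, one bin letter per ring residue.
#' @export
torsion_bins <- function(backbone) {
  res <- backbone$residues
  und <- which(is.na(res$phi) | is.na(res$psi) | is.na(res$omega))
  if (length(und))
    stop("undefined torsion at residue(s): ", paste(und, collapse = ", "))
  paste(torsion_bin(res$phi, res$psi, res$omega), collapse = "")
}

# ---- backbone H-bond fingerprint -------------------------------------------

#' Backbone hydrogen-bond fingerprint
#'
#' Ordered (donor residue, acceptor residue) pairs (i, j) such that backbone
#' N(i)-H(i) donates to carbonyl O(j) under the shared H-bond criterion
#' (heavy-atom N-O distance and N-H...O angle; see [hbond_criterion()]).
#' Pairs j in {i, i-1} are excluded (covalently constrained across the amide).
#'
#' @param backbone a [peptide_backbone()].
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `donor`, `acceptor` (residue indices),
#'   class `hbond_fingerprint`.
#' @export
hbond_fingerprint <- function(backbone, criterion = hbond_criterion()) {
  n <- backbone$ring_size
  at <- backbone$atoms
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j == i || j == i - 1) next
    Nx <- .atom_xyz(at, i, "N"); Ox <- .atom_xyz(at, j, "O")
    d <- sqrt(sum((Nx - Ox)^2))
    if (d > criterion$max_distance) next
    Hx <- .atom_xyz(at, i, "H")
    ang <- bond_angle(Nx, Hx, Ox)
    if (ang >= criterion$min_angle)
      pairs[[length(pairs) + 1]] <- c(i, j)
  }
  fp <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(donor = m[, 1], acceptor = m[, 2])
  } else data.frame(donor = integer(), acceptor = integer())
  fp <- fp[order(fp$donor, fp$acceptor), , drop = FALSE]
  rownames(fp) <- NULL
  class(fp) <- c("hbond_fingerprint", "data.frame")
  fp
}

#' Canonical string form of an H-bond fingerprint
#' @param fp an `hbond_fingerprint`.
#' @return single string like `"1>4,2>5"` (or `"-"` when empty).
#' @export
fingerprint_string <- function(fp) {
  if (!nrow(fp)) return("-")
  paste(paste0(fp$donor, ">", fp$acceptor), collapse = ",")
}

# ---- clustering -------------------------------------------------------------

.ring_backbone_coords <- function(backbone) {
  at <- backbone$atoms
  sel <- at$res_idx > 0 & at$name %in% c("N", "CA", "C", "O")
  as.matrix(at[sel, c("x", "y", "z")])
}

#' Superposed ring-backbone RMSD between two macrocycles
#' @param a,b [peptide_backbone()] objects of equal ring size.
#' @return RMSD, Angstrom, after Kabsch superposition of ring N/CA/C/O atoms.
#' @export
backbone_rmsd <- function(a, b) {
  kabsch(.ring_backbone_coords(a), .ring_backbone_coords(b))$rmsd
}

#' Cluster a macrocycle library on (torsion-bin string, H-bond fingerprint)
#'
#' Exact grouping on the composite key; the representative of each cluster is
#' the medoid under superposed ring-backbone-atom RMSD (score-independent by
#' design). Cluster order is deterministic (sorted keys); membership is
#' invariant to library order.
#'
#' @param library list of [peptide_backbone()] objects of one ring size.
#' @param criterion [hbond_criterion()] used for fingerprints.
#' @return list of clusters, each a list with `key`, `bins`, `fingerprint`,
#'   `members` (library indices) and `representative` (library index).
#' @export
cluster_backbones <- function(library, criterion = hbond_criterion()) {
  if (!length(library)) stop("empty backbone library")
  sizes <- vapply(library, function(b) b$ring_size, 0L)
  if (length(unique(sizes)) != 1L)
    stop("mixed ring sizes in library: ", paste(unique(sizes), collapse = ", "))
  bins <- vapply(library, torsion_bins, "")
  fps <- vapply(library, function(b)
    fingerprint_string(hbond_fingerprint(b, criterion)), "")
  key <- paste(bins, fps, sep = "|")
  groups <- split(seq_along(library), key)
  groups <- groups[order(names(groups))]
  lapply(names(groups), function(k) {
    members <- groups[[k]]
    rep_idx <- if (length(members) <= 2L) members[1] else {
      dm <- matrix(0, length(members), length(members))
      for (p in seq_along(members)) for (q in seq_along(members)) {
        if (q > p) {
          dm[p, q] <- dm[q, p] <-
            backbone_rmsd(library[[members[p]]], library[[members[q]]])
        }
      }
      members[which.min(rowSums(dm))]
    }
    list(key = k,
         bins = strsplit(k, "|", fixed = TRUE)[[1]][1],
         fingerprint = strsplit(k, "|", fixed = TRUE)[[1]][2],
         members = members, representative = rep_idx)
  })
}

# ---- library serialization --------------------------------------------------

#' Convert a backbone to a structure3d (chain "B")
#' @param backbone a [peptide_backbone()].
#' @return a [structure3d()].
#' @export
backbone_as_structure <- function(backbone) {
  at <- backbone$atoms
  resname <- ifelse(at$res_idx == 0, "BAC",
                    backbone$residues$name3[pmax(at$res_idx, 1)])
  structure3d(data.frame(chain = "B", resno = at$res_idx, resname = resname,
                         name = at$name, element = at$element,
                         x = at$x, y = at$y, z = at$z,
                         stringsAsFactors = FALSE))
}

#' Write a backbone library as multi-model PDB plus a sidecar table
#'
#' @param library list of [peptide_backbone()] (uniform ring size).
#' @param pdb_path multi-model PDB output path.
#' @param tsv_path tab-separated sidecar (sample id, seed, bin string,
#'   fingerprint, closure residuals).
#' @return invisibly, the sidecar data.frame.
#' @export
write_backbone_library <- function(library, pdb_path, tsv_path) {
  s1 <- backbone_as_structure(library[[1]])
  models <- lapply(library, function(b)
    as.matrix(b$atoms[, c("x", "y", "z")]))
  write_pdb(structure3d(s1$atoms, models = models), pdb_path)
  side <- data.frame(
    id = seq_along(library),
    seed = vapply(library, function(b) as.numeric(b$provenance$seed %||% NA), 0),
    bins = vapply(library, torsion_bins, ""),
    fingerprint = vapply(library, function(b)
      fingerprint_string(hbond_fingerprint(b)), ""),
    closure_bond = vapply(library, function(b) b$closure$bond, 0),
    closure_angle = vapply(library, function(b) b$closure$angle, 0))
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(side)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
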