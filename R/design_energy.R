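# Simplified physical score function and Monte-Carlo sequence design. The
# functional forms, weights and atom-type tables are declared here and make no
# claim of matching any external force field or design suite.

#' Score-function weights
#'
#' @param w_lj_atr,w_lj_rep,w_hbond,w_elec non-negative term weights.
#'   Electrostatics use a distance-dependent dielectric epsilon = 4r.
#' @return object of class `energy_weights`.
#' @export
energy_weights <- function(w_lj_atr = 1.0, w_lj_rep = 0.55, w_hbond = 1.0,
                           w_elec = 0.7) {
  w <- c(w_lj_atr = w_lj_atr, w_lj_rep = w_lj_rep, w_hbond = w_hbond,
         w_elec = w_elec)
  if (any(w < 0)) stop("energy weights must be >= 0")
  structure(as.list(w), class = "energy_weights")
}

.lj_eps <- 0.2
.energy_cutoff <- 10.0

.covalent_radii <- c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, S = 1.02,
                     P = 1.06, F = 0.71, CL = 0.99, BR = 1.14, I = 1.33)

# ---- energy atom table ------------------------------------------------------

#' Coerce to an energy atom table
#'
#' The common currency of the scoring and interface-metric code: one row per
#' atom with coordinates, vdW `radius`, partial `charge`, `donor`/`acceptor`
#' flags, residue bookkeeping (`group`, `res_idx`), and polar-geometry columns
#' (`h_x/y/z` for an attached hydrogen, `ant_x/y/z` for the bonded antecedent
#' heavy atom) used by the H-bond criterion.
#'
#' @param x a data.frame, [structure3d()], [peptide_backbone()] or
#'   `conjugate_model`.
#' @param ... unused.
#' @return data.frame of class `energy_atoms`.
#' @export
as_energy_atoms <- function(x, ...) UseMethod("as_energy_atoms")

#' @export
as_energy_atoms.energy_atoms <- function(x, ...) x

#' @export
as_energy_atoms.data.frame <- function(x, ...) {
  need <- c("name", "element", "x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (!"group" %in% names(x)) x$group <- "all"
  if (!"res_idx" %in% names(x)) x$res_idx <- seq_len(nrow(x))
  if (!"radius" %in% names(x)) x$radius <- atom_radius(x$element)
  if (any(!is.finite(x$radius)) || any(x$radius <= 0)) {
    bad <- x$element[!is.finite(x$radius) | x$radius <= 0]
    stop("missing/invalid radius for atom type(s): ",
         paste(unique(bad), collapse = ", "))
  }
  if (!"charge" %in% names(x)) x$charge <- atom_charge(x$name, x$element)
  if (!"donor" %in% names(x)) x$donor <- toupper(x$element) == "N"
  if (!"acceptor" %in% names(x)) x$acceptor <- toupper(x$element) == "O"
  x <- .polar_geometry(x)
  class(x) <- c("energy_atoms", "data.frame")
  x
}

#' @export
as_energy_atoms.structure3d <- function(x, ...) {
  at <- x$atoms
  key <- residue_key(at$chain, at$resno, at$insert)
  df <- data.frame(group = "all", res_idx = match(key, unique(key)),
                   name = at$name, element = at$element,
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  as_energy_atoms(df)
}

#' @export
as_energy_atoms.peptide_backbone <- function(x, ...) {
  at <- x$atoms
  df <- data.frame(group = "peptide", res_idx = at$res_idx, name = at$name,
                   element = at$element, x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  as_energy_atoms(df)
}

# bond adjacency by covalent-radius distance rule; across residues only
# chemically valid patterns count as bonds (backbone/link amide C-N, the
# bromoacetyl CL-N, the thioether SG-CM, and X-H), so a mere steric clash
# between unrelated atoms is never mistaken for a bond
.bond_pairs <- function(xyz, element, name = NULL, res = NULL) {
  rc <- .covalent_radii[toupper(element)]
  rc[is.na(rc)] <- 0.77
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), ncol = 2))
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") + 0.45
  w <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  if (!is.null(name) && !is.null(res) && nrow(w)) {
    pat <- function(a, b, p1, p2)
      (name[a] %in% p1 & name[b] %in% p2) | (name[a] %in% p2 & name[b] %in% p1)
    i <- w[, 1]; j <- w[, 2]
    ok <- res[i] == res[j] |
      pat(i, j, c("C", "CL"), "N") |
      pat(i, j, "SG", "CM") |
      toupper(element[i]) == "H" | toupper(element[j]) == "H"
    w <- w[ok, , drop = FALSE]
  }
  w
}

# fill h_*/ant_* columns for donors/acceptors from the bond graph; H atoms
# attached to a donor make the donor-H-acceptor convention available
.polar_geometry <- function(at) {
  n <- nrow(at)
  for (cn in c("h_x", "h_y", "h_z", "ant_x", "ant_y", "ant_z"))
    if (!cn %in% names(at)) at[[cn]] <- NA_real_
  xyz <- as.matrix(at[, c("x", "y", "z")])
  bp <- .bond_pairs(xyz, at$element, at$name, paste(at$group, at$res_idx))
  if (!nrow(bp)) return(at)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(bp))) {
    i <- bp[r, 1]; j <- bp[r, 2]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  ish <- toupper(at$element) == "H"
  for (i in which((at$donor | at$acceptor) & !ish)) {
    nb <- nbr[[i]]
    if (is.null(nb)) next
    hs <- nb[ish[nb]]
    heav <- nb[!ish[nb]]
    if (length(hs) && is.na(at$h_x[i]))
      at[i, c("h_x", "h_y", "h_z")] <- xyz[hs[1], ]
    if (length(heav) && is.na(at$ant_x[i]))
      at[i, c("ant_x", "ant_y", "ant_z")] <- xyz[heav[1], ]
  }
  at
}

# ---- pair energies ----------------------------------------------------------

# LJ split into attractive/repulsive parts: at r >= r0 the full well
# (attractive branch); inside r0 the repulsion above the well depth.
.lj_terms <- function(r, r0) {
  s6 <- (r0 / r)^6
  lj <- .lj_eps * (s6^2 - 2 * s6)
  atr <- ifelse(r >= r0, lj, -.lj_eps)
  rep <- ifelse(r < r0, lj + .lj_eps, 0)
  list(atr = atr, rep = rep)
}

# exclusion: same residue, or within 2 covalent bonds across residues
.exclusion_matrix <- function(at) {
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  reskey <- paste(at$group, at$res_idx)
  excl <- outer(reskey, reskey, "==")
  bp <- .bond_pairs(xyz, at$element, at$name, reskey)
  adj <- matrix(FALSE, n, n)
  if (nrow(bp)) {
    adj[bp] <- TRUE; adj[bp[, c(2, 1), drop = FALSE]] <- TRUE
    one3 <- (adj %*% adj) > 0
    excl <- excl | adj | one3
  }
  diag(excl) <- TRUE
  excl
}

.count_hbonds <- function(at, criterion = hbond_criterion(),
                          subset = NULL, cross_groups_only = FALSE) {
  don <- which(at$donor & toupper(at$element) != "H")
  acc <- which(at$acceptor & toupper(at$element) != "H")
  if (!length(don) || !length(acc)) return(0L)
  cnt <- 0L
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (i in don) {
    js <- acc[acc != i]
    js <- js[!(at$group[js] == at$group[i] & at$res_idx[js] == at$res_idx[i])]
    if (cross_groups_only) js <- js[at$group[js] != at$group[i]]
    if (!is.null(subset) && !(i %in% subset)) js <- js[js %in% subset]
    if (!length(js)) next
    dv <- sweep(xyz[js, , drop = FALSE], 2, xyz[i, ])
    d <- sqrt(rowSums(dv^2))
    js <- js[d <= criterion$max_distance]
    if (!length(js)) next
    hx <- as.numeric(at[i, c("h_x", "h_y", "h_z")])
    ax <- as.numeric(at[i, c("ant_x", "ant_y", "ant_z")])
    use_h <- criterion$vertex == "hydrogen" && all(is.finite(hx))
    if (!use_h && any(!is.finite(ax))) next
    for (j in js) {
      ang <- if (use_h) bond_angle(xyz[i, ], hx, xyz[j, ])
             else bond_angle(ax, xyz[i, ], xyz[j, ])
      if (ang >= criterion$min_angle) cnt <- cnt + 1L
    }
  }
  cnt
}

#' Total energy of an atom set under the declared score function
#'
#' `E = sum over non-bonded pairs within 10 A of
#' [w_lj_atr * LJatr + w_lj_rep * LJrep + w_elec * q_i q_j / (4 r^2)]
#'  - w_hbond * (number of hydrogen bonds under the shared criterion)`,
#' with `LJ(r) = eps[(r0/r)^12 - 2 (r0/r)^6]`, `eps = 0.2`, `r0 = r_i + r_j`.
#' Pairs in the same residue or within two covalent bonds are excluded.
#'
#' @param x anything [as_energy_atoms()] accepts.
#' @param weights an [energy_weights()].
#' @param criterion an [hbond_criterion()].
#' @return energy, arbitrary units.
#' @export
total_energy <- function(x, weights = energy_weights(),
                         criterion = hbond_criterion()) {
  at <- as_energy_atoms(x)
  heavy <- toupper(at$element) != "H"
  ath <- at[heavy, , drop = FALSE]
  n <- nrow(ath)
  if (n < 2) return(0)
  xyz <- as.matrix(ath[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  excl <- .exclusion_matrix(ath)
  use <- upper.tri(d) & !excl & d <= .energy_cutoff & d > 1e-6
  if (!any(use)) {
    e_pair <- 0
  } else {
    r <- d[use]
    r0 <- outer(ath$radius, ath$radius, "+")[use]
    lj <- .lj_terms(r, r0)
    qq <- outer(ath$charge, ath$charge)[use]
    e_pair <- sum(weights$w_lj_atr * lj$atr + weights$w_lj_rep * lj$rep +
                  weights$w_elec * qq / (4 * r * r))
  }
  e_pair - weights$w_hbond * .count_hbonds(at, criterion)
}

# interaction energy of a subset of atoms (rows `sel`) with all other atoms,
# plus the subset-involving H-bond term; used for incremental design moves
.subset_energy <- function(at, sel, weights, criterion = hbond_criterion()) {
  if (!length(sel)) return(0)
  heavy <- which(toupper(at$element) != "H")
  sel <- intersect(sel, heavy)
  oth <- setdiff(heavy, sel)
  if (!length(sel) || !length(oth)) return(0)
  A <- as.matrix(at[sel, c("x", "y", "z")])
  B <- as.matrix(at[oth, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  same_res <- outer(paste(at$group[sel], at$res_idx[sel]),
                    paste(at$group[oth], at$res_idx[oth]), "==")
  use <- !same_res & d <= .energy_cutoff & d > 1e-6
  e <- 0
  if (any(use)) {
    r <- d[use]
    r0 <- outer(at$radius[sel], at$radius[oth], "+")[use]
    lj <- .lj_terms(r, r0)
    qq <- outer(at$charge[sel], at$charge[oth])[use]
    e <- sum(weights$w_lj_atr * lj$atr + weights$w_lj_rep * lj$rep +
             weights$w_elec * qq / (4 * r * r))
  }
  e - weights$w_hbond * .count_hbonds(at, criterion, subset = sel)
}

# ---- sequence design by simulated annealing ---------------------------------

#' Monte-Carlo sequence design on a grafted conjugate
#'
#' Simulated annealing over (identity, rotamer) moves at the designable
#' peptide positions with Metropolis acceptance and a geometric temperature
#' schedule (T from `t_hi` to `t_lo` over `50 * n_positions` moves per outer
#' round). The chirality of a position is restricted to match its torsion
#' bin (positive-phi bins admit D only; negative-phi bins L only; cis bins
#' both). Deterministic under `seed`; returns the best-visited state.
#'
#' @param model a `conjugate_model` (see [graft()]).
#' @param designable_positions ring positions to design; defaults to all ring
#'   residues except the bridge Cys. The anchor-proximal D-Phe lives on the
#'   tail and is never designable.
#' @param identities candidate identities (default [designable_identities()]).
#' @param weights an [energy_weights()].
#' @param n_outer_rounds annealing rounds (default 3).
#' @param seed integer RNG seed.
#' @param t_hi,t_lo temperature schedule endpoints.
#' @return object of class `design_result`: `sequence` (data.frame of
#'   position/identity/chirality/chi1/chi2), `energy`, `trace` (best-so-far
#'   energy after each accepted move), `model` (with final side chains),
#'   `seed`.
#' @export
design_sequence <- function(model, designable_positions = NULL,
                            identities = designable_identities(),
                            weights = energy_weights(), n_outer_rounds = 3L,
                            seed = 1L, t_hi = 3.0, t_lo = 0.3) {
  stopifnot(inherits(model, "conjugate_model"))
  n <- model$ring_size
  if (is.null(designable_positions))
    designable_positions <- setdiff(seq_len(n), n)
  if (any(designable_positions == n))
    stop("the bridge Cys position cannot be designed")
  e_now <- total_energy(model$atoms, weights)
  if (!length(designable_positions)) {
    return(structure(list(sequence = .model_sequence(model), energy = e_now,
                          trace = e_now, model = model, seed = seed),
                     class = "design_result"))
  }
  bins <- strsplit(model$peptide_bins, "")[[1]]
  allowed_chir <- function(pos) {
    switch(bins[pos], A = "L", B = "L", G = "D", E = "D", O = c("L", "D"))
  }
  .with_seed(seed, {
    best <- list(atoms = model$atoms, seq = model$peptide_seq, e = e_now)
    cur <- best
    trace <- e_now
    n_moves <- 50L * length(designable_positions)
    for (round in seq_len(n_outer_rounds)) {
      temps <- t_hi * (t_lo / t_hi)^((seq_len(n_moves) - 1) / max(1, n_moves - 1))
      for (m in seq_len(n_moves)) {
        pos <- designable_positions[sample.int(length(designable_positions), 1)]
        chir <- sample(allowed_chir(pos), 1)
        id <- sample(identities, 1)
        rots <- rotamer_set(id, chir)
        rot <- rots[sample.int(nrow(rots), 1), , drop = FALSE]
        at_cur <- cur$atoms
        old_rows <- which(at_cur$group == "peptide" & at_cur$res_idx == pos &
                          at_cur$sc)
        e_old <- .subset_energy(at_cur, old_rows, weights)
        at_new <- .swap_sidechain(at_cur, model, pos, id, chir, rot)
        new_rows <- which(at_new$group == "peptide" & at_new$res_idx == pos &
                          at_new$sc)
        e_new <- .subset_energy(at_new, new_rows, weights)
        dE <- e_new - e_old
        if (dE <= 0 || stats::runif(1) < exp(-dE / temps[m])) {
          cur$atoms <- at_new
          cur$e <- cur$e + dE
          cur$seq[[pos]] <- list(identity = id, chirality = chir,
                                 chi1 = rot$chi1, chi2 = rot$chi2)
          if (cur$e < best$e) best <- cur
          trace <- c(trace, best$e)
        }
      }
    }
    out_model <- model
    out_model$atoms <- best$atoms
    out_model$peptide_seq <- best$seq
    structure(list(sequence = .model_sequence(out_model),
                   energy = best$e, trace = trace, model = out_model,
                   seed = seed),
              class = "design_result")
  })
}

#' @export
print.design_result <- function(x, ...) {
  s <- x$sequence
  cat("design_result:",
      paste(ifelse(s$chirality == "D", paste0("d", tolower(s$identity)),
                   s$identity), collapse = "-"),
      sprintf(" E = %.3f (%d accepted moves)\n", x$energy, length(x$trace) - 1))
  invisible(x)
}

.model_sequence <- function(model) {
  n <- model$ring_size
  do.call(rbind, lapply(seq_len(n), function(i) {
    s <- model$peptide_seq[[i]]
    data.frame(position = i, identity = s$identity, chirality = s$chirality,
               chi1 = if (is.null(s$chi1)) NA_real_ else as.numeric(s$chi1),
               chi2 = if (is.null(s$chi2)) NA_real_ else as.numeric(s$chi2),
               stringsAsFactors = FALSE)
  }))
}

#' Set the side chain at one peptide position of a conjugate model
#'
#' Replaces the coarse side-chain pseudo-atoms at a ring position with the
#' given identity/chirality/rotamer and updates the model's sequence state.
#' Used by the annealer internally and exposed for exhaustive enumeration.
#'
#' @param model a `conjugate_model`.
#' @param position ring position (1-based; not the bridge Cys).
#' @param identity three-letter code.
#' @param chirality "L" or "D".
#' @param chi1,chi2 chi angles, degrees (NA where the identity has fewer
#'   pseudo-atoms).
#' @return the updated model.
#' @export
set_sidechain <- function(model, position, identity, chirality = "L",
                          chi1 = NA_real_, chi2 = NA_real_) {
  stopifnot(inherits(model, "conjugate_model"))
  if (position == model$ring_size) stop("the bridge Cys cannot be redesigned")
  rot <- data.frame(chi1 = chi1, chi2 = chi2)
  model$atoms <- .swap_sidechain(model$atoms, model, position, identity,
                                 chirality, rot)
  model$peptide_seq[[position]] <- list(identity = identity,
                                        chirality = chirality,
                                        chi1 = chi1, chi2 = chi2)
  model
}

# replace the side-chain pseudo-atoms of one peptide position
.swap_sidechain <- function(at, model, pos, identity, chirality, rotamer) {
  keep <- !(at$group == "peptide" & at$res_idx == pos & at$sc)
  at2 <- at[keep, , drop = FALSE]
  bb <- function(nm) {
    i <- which(at$group == "peptide" & at$res_idx == pos & at$name == nm & !at$sc)
    as.numeric(at[i[1], c("x", "y", "z")])
  }
  sc <- .build_sidechain(identity, bb("N"), bb("CA"), bb("CB"), rotamer)
  if (!is.null(sc)) {
    ant <- bb("CB")
    rows <- data.frame(group = "peptide", res_idx = pos, name = sc$name,
                       element = sc$element, x = sc$x, y = sc$y, z = sc$z,
                       radius = sc$radius, charge = sc$charge,
                       donor = sc$donor, acceptor = sc$acceptor,
                       sc = TRUE,
                       h_x = NA_real_, h_y = NA_real_, h_z = NA_real_,
                       ant_x = NA_real_, ant_y = NA_real_, ant_z = NA_real_,
                       stringsAsFactors = FALSE)
    # antecedent chain: CB for the first pseudo-atom, then the previous one
    rows[1, c("ant_x", "ant_y", "ant_z")] <- ant
    if (nrow(rows) > 1)
      rows[2, c("ant_x", "ant_y", "ant_z")] <- c(sc$x[1], sc$y[1], sc$z[1])
    common <- intersect(names(at2), names(rows))
    at2 <- rbind(at2[, common, drop = FALSE], rows[, common, drop = FALSE])
  }
  class(at2) <- class(at)
  at2
}
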