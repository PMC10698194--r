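# Dipeptide extension of the small-molecule anchor, rigid-body grafting of
# macrocycles by 5-atom Kabsch superposition, and the clash screen.

#' Small-molecule anchor stub
#'
#' The rigid anchor (a morphinan-like core stripped to leave a free amine)
#' posed in the receptor frame. The attachment amine is the nitrogen to which
#' the peptide C-terminus is conjugated; `ref1`/`ref2` are two stub heavy
#' atoms bonded toward the amine, used to define the extension build frame.
#' The stub pose is immutable during extension sampling.
#'
#' @param atoms data.frame with `name`, `element`, `x`, `y`, `z`.
#' @param attachment_amine name of the attachment nitrogen atom.
#' @param ref1,ref2 names of two stub atoms defining the amine frame
#'   (`ref2` bonded to the amine, `ref1` bonded to `ref2`).
#' @return object of class `anchor_stub`.
#' @export
anchor_stub <- function(atoms, attachment_amine = "N1",
                        ref1 = "C2", ref2 = "C1") {
  for (nm in c(attachment_amine, ref1, ref2))
    if (!nm %in% atoms$name) stop("anchor atom not found: ", nm)
  i <- match(attachment_amine, atoms$name)
  if (toupper(atoms$element[i]) != "N")
    stop("attachment_amine must be a nitrogen")
  structure(list(atoms = atoms, attachment_amine = attachment_amine,
                 ref1 = ref1, ref2 = ref2),
            class = "anchor_stub")
}

#' @export
print.anchor_stub <- function(x, ...) {
  cat("anchor_stub:", nrow(x$atoms), "atoms, attachment amine",
      x$attachment_amine, "\n")
  invisible(x)
}

.anchor_xyz <- function(anchor, name) {
  as.numeric(anchor$atoms[match(name, anchor$atoms$name), c("x", "y", "z")])
}

# Build dipeptide extension atoms off the anchor amine, C-terminus-first:
# E1 (anchor-proximal, fixed D-Phe) then E2 (sampled identity/chirality).
# tors = c(t0, psi1, phi1, psi2); chi = list(e1 = rotamer row, e2 = rotamer row)
.build_extension_atoms <- function(anchor, id2, chir2, tors, chi) {
  g <- .geom
  Natt <- .anchor_xyz(anchor, anchor$attachment_amine)
  r2 <- .anchor_xyz(anchor, anchor$ref2)
  r1 <- .anchor_xyz(anchor, anchor$ref1)
  C1 <- place_atom(r1, r2, Natt, g$n_cl, 120, tors[1])
  CA1 <- place_atom(r2, Natt, C1, g$ca_c, g$ang_ca_c_n, 180)
  O1 <- place_atom(r2, Natt, C1, g$c_o, 123, 0)
  N1 <- place_atom(Natt, C1, CA1, g$n_ca, g$ang_n_ca_c, tors[2])   # psi1
  CB1 <- place_atom(N1, C1, CA1, g$ca_cb, g$ang_c_ca_cb, -g$chir_improper) # D
  C2 <- place_atom(C1, CA1, N1, g$c_n, g$ang_c_n_ca, tors[3])      # phi1
  H1 <- place_atom(CA1, C2, N1, g$n_h, 119, 180)
  CA2 <- place_atom(CA1, N1, C2, g$ca_c, g$ang_ca_c_n, 180)        # omega
  O2 <- place_atom(CA1, N1, C2, g$c_o, 123, 0)
  N2 <- place_atom(N1, C2, CA2, g$n_ca, g$ang_n_ca_c, tors[4])     # psi2
  sgn2 <- if (chir2 == "D") -1 else 1
  CB2 <- place_atom(N2, C2, CA2, g$ca_cb, g$ang_c_ca_cb, sgn2 * g$chir_improper)
  bb <- rbind(
    data.frame(res_idx = 1L, name = c("C", "O", "CA", "N", "H", "CB"),
               element = c("C", "O", "C", "N", "H", "C"),
               rbind(C1, O1, CA1, N1, H1, CB1)),
    data.frame(res_idx = 2L, name = c("C", "O", "CA", "N", "CB"),
               element = c("C", "O", "C", "N", "C"),
               rbind(C2, O2, CA2, N2, CB2)))
  names(bb)[4:6] <- c("x", "y", "z")
  bb$sc <- FALSE
  bb$donor <- bb$name == "N"
  bb$acceptor <- bb$name == "O"
  bb$radius <- atom_radius(bb$element)
  bb$charge <- atom_charge(bb$name, bb$element)
  add_sc <- function(bb, res_idx, id, nx, cax, cbx, rot) {
    sc <- .build_sidechain(id, nx, cax, cbx, rot)
    if (is.null(sc)) return(bb)
    rows <- data.frame(res_idx = res_idx, name = sc$name, element = sc$element,
                       x = sc$x, y = sc$y, z = sc$z, sc = TRUE,
                       donor = sc$donor, acceptor = sc$acceptor,
                       radius = sc$radius, charge = sc$charge)
    rbind(bb, rows)
  }
  bb <- add_sc(bb, 1L, "PHE", N1, CA1, CB1, chi$e1)
  bb <- add_sc(bb, 2L, id2, N2, CA2, CB2, chi$e2)
  rownames(bb) <- NULL
  bb
}

.extension_label <- function(id2, chir2) {
  paste0("D-PHE+", chir2, "-", id2)
}

#' Enumerate dipeptide extensions off the anchor amine
#'
#' Position 1 is a fixed D-Phe (mimicking the removed aromatic group of the
#' parent ligand); position 2 sweeps all 20 amino acids excluding glycine and
#' cysteine in both L and D forms (18 x 2 = 36 identities). For each identity
#' the extension backbone torsions are sampled on a 30-degree grid, scored
#' with the declared score function (extension-internal energy plus
#' extension-receptor interaction), and the best sample is locally refined by
#' coordinate descent on the torsions. Deterministic under `seed`.
#'
#' @param anchor an [anchor_stub()] posed in the receptor frame.
#' @param receptor a [structure3d()] (may be `NULL`: scores then reduce to
#'   extension-internal energy).
#' @param torsion_samples_per_identity grid samples per identity (default 15).
#' @param seed integer RNG seed.
#' @param weights an [energy_weights()].
#' @return list of `extension_candidate` objects, each carrying `identity2`,
#'   `chirality2`, `label`, `torsions`, `score` and the extension `atoms`.
#' @export
enumerate_extensions <- function(anchor, receptor = NULL,
                                 torsion_samples_per_identity = 15L,
                                 seed = 1L, weights = energy_weights()) {
  if (torsion_samples_per_identity < 1)
    stop("torsion_samples_per_identity must be >= 1")
  rec_at <- if (is.null(receptor)) NULL else {
    ea <- as_energy_atoms(receptor)
    ea$group <- "receptor"
    ea
  }
  grid30 <- seq(-180, 150, by = 30)
  score_ext <- function(bb) {
    dip <- bb
    dip$group <- "extension"
    e_int <- total_energy(as_energy_atoms(dip), weights)
    if (is.null(rec_at)) return(e_int)
    common <- intersect(names(rec_at), names(as_energy_atoms(dip)))
    comb <- rbind(as_energy_atoms(dip)[, common], rec_at[, common])
    class(comb) <- c("energy_atoms", "data.frame")
    sel <- which(comb$group == "extension")
    e_int + .subset_energy(comb, sel, weights)
  }
  ids <- designable_identities()
  .with_seed(seed, {
    cands <- list()
    for (id2 in ids) for (chir2 in c("L", "D")) {
      chi <- list(e1 = rotamer_set("PHE", "D")[1, , drop = FALSE],
                  e2 = rotamer_set(id2, chir2)[1, , drop = FALSE])
      best <- NULL
      for (s in seq_len(torsion_samples_per_identity)) {
        tors <- sample(grid30, 4, replace = TRUE)
        bb <- .build_extension_atoms(anchor, id2, chir2, tors, chi)
        sc <- score_ext(bb)
        if (is.null(best) || sc < best$score)
          best <- list(tors = tors, score = sc, atoms = bb)
      }
      # local coordinate descent on the four torsions
      for (k in 1:4) {
        for (dth in c(-15, -10, -5, 5, 10, 15)) {
          tt <- best$tors; tt[k] <- .wrap180(tt[k] + dth)
          bb <- .build_extension_atoms(anchor, id2, chir2, tt, chi)
          sc <- score_ext(bb)
          if (sc < best$score) best <- list(tors = tt, score = sc, atoms = bb)
        }
      }
      cands[[length(cands) + 1]] <- structure(
        list(identity2 = id2, chirality2 = chir2,
             label = .extension_label(id2, chir2),
             torsions = best$tors, score = best$score, atoms = best$atoms,
             chi = chi),
        class = "extension_candidate")
    }
    cands
  })
}

#' Rank extension candidates by binding score
#'
#' Ascending score; exact ties broken lexicographically by identity label so
#' the order is a permutation-stable total order.
#'
#' @param candidates list from [enumerate_extensions()].
#' @param keep number to keep (default 4, the design campaign's choice).
#' @return list of the top-`keep` candidates.
#' @export
rank_extensions <- function(candidates, keep = 4L) {
  if (keep <= 0) stop("keep must be > 0")
  sc <- vapply(candidates, function(c) c$score, 0)
  lb <- vapply(candidates, function(c) c$label, "")
  ord <- order(sc, lb)
  if (keep > length(candidates)) {
    warning("keep exceeds number of candidates; returning all")
    keep <- length(candidates)
  }
  candidates[ord[seq_len(keep)]]
}

#' Graft frame at the tail N-terminus of an extension
#'
#' Builds a temporary, ideal-geometry pseudo-Cys residue whose carbonyl bonds
#' the extension's position-2 nitrogen, exposing the 5 named atoms
#' (C, N, O, CA, CB) that [graft()] superposes the macrocycle's C-terminal
#' Cys onto.
#'
#' @param extension an `extension_candidate`.
#' @param chirality chirality of the pseudo-Cys ("L" or "D").
#' @param phi2 torsion placing the pseudo-carbonyl about position 2's N-CA
#'   bond, degrees.
#' @param psi_g psi-like torsion of the pseudo-residue, degrees.
#' @return 5 x 3 matrix with rownames C, N, O, CA, CB.
#' @export
extension_graft_frame <- function(extension, chirality = "L",
                                  phi2 = -120, psi_g = 140) {
  g <- .geom
  bb <- extension$atoms
  gx <- function(ri, nm)
    as.numeric(bb[bb$res_idx == ri & bb$name == nm, c("x", "y", "z")][1, ])
  C2 <- gx(2, "C"); CA2 <- gx(2, "CA"); N2 <- gx(2, "N")
  Cg <- place_atom(C2, CA2, N2, g$c_n, g$ang_c_n_ca, phi2)
  CAg <- place_atom(CA2, N2, Cg, g$ca_c, g$ang_ca_c_n, 180)
  Og <- place_atom(CA2, N2, Cg, g$c_o, 123, 0)
  Ng <- place_atom(N2, Cg, CAg, g$n_ca, g$ang_n_ca_c, psi_g)
  sgn <- if (chirality == "D") -1 else 1
  CBg <- place_atom(Ng, Cg, CAg, g$ca_cb, g$ang_c_ca_cb, sgn * g$chir_improper)
  m <- rbind(C = Cg, N = Ng, O = Og, CA = CAg, CB = CBg)
  m
}

.backbone_graft_frame <- function(backbone) {
  n <- backbone$ring_size
  at <- backbone$atoms
  m <- rbind(C = .atom_xyz(at, n, "C"),
             N = .atom_xyz(at, n, "N"),
             O = .atom_xyz(at, n, "O"),
             CA = .atom_xyz(at, n, "CA"),
             CB = .atom_xyz(at, n, "CB"))
  m
}

#' Graft a macrocycle onto an anchor frame
#'
#' Superposes the C, N, O, CA, CB atoms of the macrocycle's C-terminal Cys
#' onto the corresponding atoms of the anchor-side frame (Kabsch, proper
#' rotation only) and applies the rigid transform to the whole macrocycle —
#' a rigid motion, so all peptide-internal distances are preserved. Models
#' whose 5-atom alignment RMSD exceeds `rmsd_max` are rejected: the failure
#' is a value of class `graft_failure` carrying the RMSD.
#'
#' @param backbone a closed [peptide_backbone()].
#' @param anchor_frame 5 x 3 matrix with rownames C, N, O, CA, CB (see
#'   [extension_graft_frame()]).
#' @param rmsd_max alignment-RMSD rejection threshold, Angstrom (default
#'   0.75).
#' @return the transformed backbone with `graft_rmsd` set, or a
#'   `graft_failure`.
#' @export
graft <- function(backbone, anchor_frame, rmsd_max = 0.75) {
  need <- c("C", "N", "O", "CA", "CB")
  if (is.null(rownames(anchor_frame)) || !all(need %in% rownames(anchor_frame)))
    stop("anchor_frame must name atoms: ",
         paste(setdiff(need, rownames(anchor_frame)), collapse = ", "))
  moving <- .backbone_graft_frame(backbone)
  fit <- kabsch(moving[need, ], anchor_frame[need, ])
  if (fit$rmsd > rmsd_max) {
    return(structure(list(success = FALSE, rmsd = fit$rmsd),
                     class = "graft_failure"))
  }
  at <- backbone$atoms
  xyz <- apply_transform(fit$transform, as.matrix(at[, c("x", "y", "z")]))
  # rigid link correction: translate so the terminal carbonyl C lands exactly
  # on the frame C, preserving the amide-link geometry the frame encodes
  i_c <- which(at$res_idx == backbone$ring_size & at$name == "C")
  xyz <- sweep(xyz, 2, anchor_frame["C", ] - xyz[i_c, ], "+")
  at[, c("x", "y", "z")] <- xyz
  backbone$atoms <- at
  backbone$graft_rmsd <- fit$rmsd
  backbone
}

#' Assemble a receptor / anchor / grafted-peptide conjugate model
#'
#' Flattens receptor, anchor stub, extension tail and grafted macrocycle into
#' one energy atom table (groups "receptor", "anchor", "peptide"), verifies
#' the amide link geometry (peptide C-terminal carbonyl to extension
#' nitrogen, 1.33 +/- 0.2 Angstrom), and seeds the peptide sequence state for
#' design.
#'
#' @param receptor a [structure3d()] with loop annotations.
#' @param anchor an [anchor_stub()].
#' @param extension an `extension_candidate` (may be `NULL` when the anchor
#'   frame is used directly).
#' @param peptide a grafted [peptide_backbone()].
#' @return object of class `conjugate_model`.
#' @export
conjugate_model <- function(receptor, anchor, extension, peptide) {
  rec <- as_energy_atoms(receptor)
  rec$group <- "receptor"; rec$sc <- FALSE
  an <- anchor$atoms
  an$group <- "anchor"; an$res_idx <- 0L; an$sc <- FALSE
  an$radius <- atom_radius(an$element)
  an$charge <- atom_charge(an$name, an$element)
  an$donor <- toupper(an$element) == "N"
  an$acceptor <- toupper(an$element) == "O"
  tabs <- list(rec, an)
  if (!is.null(extension)) {
    ex <- extension$atoms
    ex$group <- "anchor"
    ex$res_idx <- ex$res_idx  # 1 = D-Phe (anchor-proximal), 2 = sampled
    tabs <- c(tabs, list(ex))
  }
  pp <- peptide$atoms
  pp$group <- "peptide"
  pp$sc <- pp$name == "SG"
  pp$donor <- pp$name == "N"
  pp$acceptor <- pp$name %in% c("O", "OL")
  pp$radius <- atom_radius(pp$element)
  pp$charge <- atom_charge(pp$name, pp$element)
  common <- Reduce(intersect, lapply(tabs, names))
  common <- intersect(c("group", "res_idx", "name", "element", "x", "y", "z",
                        "sc", "radius", "charge", "donor", "acceptor"), common)
  at <- do.call(rbind, c(lapply(tabs, function(t) t[, common, drop = FALSE]),
                         list(pp[, common, drop = FALSE])))
  rownames(at) <- NULL
  class(at) <- "data.frame"  # force re-derivation of polar geometry columns
  at <- as_energy_atoms(at)
  model <- structure(list(
    atoms = at, receptor = receptor, anchor = anchor, extension = extension,
    peptide = peptide, ring_size = peptide$ring_size,
    peptide_bins = torsion_bins(peptide),
    peptide_seq = lapply(seq_len(peptide$ring_size), function(i)
      list(identity = peptide$residues$name3[i],
           chirality = peptide$residues$chirality[i],
           chi1 = NA_real_, chi2 = NA_real_)),
    graft_rmsd = peptide$graft_rmsd %||% NA_real_,
    link = NULL), class = "conjugate_model")
  # link geometry: peptide C-terminal C to extension position-2 N
  if (!is.null(extension)) {
    cx <- .atom_xyz(peptide$atoms, peptide$ring_size, "C")
    ex <- extension$atoms
    nx <- as.numeric(ex[ex$res_idx == 2 & ex$name == "N", c("x", "y", "z")][1, ])
    model$link <- list(length = sqrt(sum((cx - nx)^2)), target = 1.33,
                       tol = 0.2)
  }
  model
}

#' @export
print.conjugate_model <- function(x, ...) {
  cat(sprintf("conjugate_model: %d atoms (receptor %d / anchor %d / peptide %d), ring %d-mer, bins %s\n",
              nrow(x$atoms), sum(x$atoms$group == "receptor"),
              sum(x$atoms$group == "anchor"), sum(x$atoms$group == "peptide"),
              x$ring_size, x$peptide_bins))
  if (!is.null(x$link))
    cat(sprintf("  amide link: %.2f A (target %.2f +/- %.2f)\n",
                x$link$length, x$link$target, x$link$tol))
  invisible(x)
}

#' Steric clash screen of a conjugate model
#'
#' A clash is a non-bonded heavy-atom pair (peptide versus receptor or
#' anchor) whose distance is below `r_i + r_j - clash_overlap`. Pairs within
#' two covalent bonds of the amide link are excluded. Counted by exhaustive
#' pair enumeration.
#'
#' @param model a `conjugate_model`.
#' @param clash_overlap allowed vdW overlap, Angstrom (default 0.4).
#' @param max_clashes pass threshold (default 5).
#' @return list with `pass` and `count`.
#' @export
clash_screen <- function(model, clash_overlap = 0.4, max_clashes = 5L) {
  at <- model$atoms
  heavy <- toupper(at$element) != "H"
  pep <- which(at$group == "peptide" & heavy)
  env <- which(at$group != "peptide" & heavy)
  if (!length(pep) || !length(env)) return(list(pass = TRUE, count = 0L))
  A <- as.matrix(at[pep, c("x", "y", "z")])
  B <- as.matrix(at[env, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  thr <- outer(at$radius[pep], at$radius[env], "+") - clash_overlap
  clash <- d < thr
  # exclude pairs covalently constrained across the amide link
  sub <- at[c(pep, env), , drop = FALSE]
  excl <- .exclusion_matrix(sub)[seq_along(pep), length(pep) + seq_along(env),
                                 drop = FALSE]
  count <- sum(clash & !excl)
  list(pass = count <= max_clashes, count = as.integer(count))
}
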