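# Deterministic synthetic fixtures: a toy receptor pocket with annotated
# loop patches, a rigid toy anchor, and jittered conformational ensembles.
# These stand in for a real receptor structure so every pipeline stage runs
# with no download; they emulate geometry (a closed cavity, a posed anchor,
# mouth-adjacent loops), not receptor physics.

#' Toy pocket specification
#'
#' @param cavity_radius probe-accessible cavity radius, Angstrom (> 0).
#' @param shell_spacing target spacing of shell pseudo-atoms, Angstrom
#'   (default 2.4; small enough that the shell is water-tight for the
#'   flood-fill at default grid).
#' @param patch_half_angle angular half-width of each loop patch, degrees.
#' @param patch_polar_angle polar angle of the patch centres from the pocket
#'   mouth axis (+z), degrees.
#' @param anchor_z z-position of the anchor attachment amine in the cavity
#'   (used by the pipeline when it builds the toy anchor).
#' @param seed RNG seed (shell construction is deterministic; the seed is
#'   recorded for provenance).
#' @return object of class `toy_pocket_spec`.
#' @export
toy_pocket_spec <- function(cavity_radius = 13.5, shell_spacing = 2.4,
                            patch_half_angle = 30, patch_polar_angle = 50,
                            anchor_z = -6, seed = 1L) {
  if (cavity_radius <= 0) stop("cavity_radius must be > 0")
  if (patch_polar_angle - patch_half_angle < 0)
    stop("loop patches would overlap the cavity mouth axis")
  structure(list(cavity_radius = cavity_radius, shell_spacing = shell_spacing,
                 patch_half_angle = patch_half_angle,
                 patch_polar_angle = patch_polar_angle,
                 anchor_z = anchor_z, seed = seed),
            class = "toy_pocket_spec")
}

#' Build the toy receptor pocket
#'
#' A closed spherical shell of carbon pseudo-atoms (one residue each, chain
#' "R") whose probe-accessible interior has the requested cavity radius; two
#' shell patches near the mouth axis are annotated "ECL2" and "ECL3" (and
#' the remainder "orthosteric"). Deterministic: the shell is a Fibonacci
#' lattice, so identical specs give identical structures.
#'
#' @param spec a [toy_pocket_spec()].
#' @param probe probe radius used to convert cavity radius to shell radius.
#' @return a [structure3d()] with annotations.
#' @export
make_toy_pocket <- function(spec = toy_pocket_spec(), probe = 1.4) {
  r_atom <- atom_radius("C")
  R <- spec$cavity_radius + r_atom + probe
  n <- max(24L, round(4 * pi * R^2 / spec$shell_spacing^2))
  sph <- .fibonacci_sphere(n)
  xyz <- sph * R
  polar <- acos(pmin(1, pmax(-1, sph[, 3]))) * 180 / pi
  azim <- atan2(sph[, 2], sph[, 1]) * 180 / pi
  in_patch <- function(az0) {
    dphi <- abs(.wrap180(azim - az0))
    polar >= spec$patch_polar_angle - spec$patch_half_angle &
      polar <= spec$patch_polar_angle + spec$patch_half_angle &
      dphi <= spec$patch_half_angle * 2
  }
  ecl2 <- in_patch(0)
  ecl3 <- in_patch(180) & !ecl2
  atoms <- data.frame(chain = "R", resno = seq_len(n), resname = "SHL",
                      name = "C", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  keys <- residue_key(atoms$chain, atoms$resno)
  structure3d(atoms,
              annotations = list(ECL2 = keys[ecl2], ECL3 = keys[ecl3],
                                 orthosteric = keys[!(ecl2 | ecl3)]))
}

#' Build the rigid toy anchor stub
#'
#' A ten-heavy-atom rigid cluster mimicking a fused-ring small molecule, with
#' a free attachment amine (N1) pointing along +z toward the pocket mouth and
#' the frame atoms C1 (bonded to N1) and C2 (bonded to C1) used to seed the
#' extension build.
#'
#' @param amine_pos position of the attachment amine, Angstrom.
#' @return an [anchor_stub()].
#' @export
make_toy_anchor <- function(amine_pos = c(0, 0, -3.5)) {
  base <- rbind(
    N1 = c(0.00, 0.00, 0.00),
    C1 = c(0.00, 0.95, -1.12),
    C2 = c(1.25, 1.10, -1.95),
    C3 = c(-1.25, 1.10, -1.95),
    C4 = c(0.65, 2.30, -2.90),
    C5 = c(-0.65, 2.30, -2.90),
    C6 = c(1.40, -0.30, -2.60),
    C7 = c(-1.40, -0.30, -2.60),
    O1 = c(0.00, 3.45, -3.30),
    C8 = c(0.00, -1.20, -2.05))
  xyz <- sweep(base, 2, amine_pos, "+")
  atoms <- data.frame(name = rownames(base),
                      element = substr(rownames(base), 1, 1),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  anchor_stub(atoms, attachment_amine = "N1", ref1 = "C2", ref2 = "C1")
}

#' Jittered conformational ensemble from a base model
#'
#' Frame i adds i.i.d. Gaussian coordinate noise to the base coordinates;
#' sigma = 0 gives identical frames. Deterministic under `seed`.
#'
#' @param base a [structure3d()] (model 1 is the base pose).
#' @param n_frames number of frames (>= 1).
#' @param sigma coordinate noise standard deviation, Angstrom (>= 0).
#' @param seed RNG seed.
#' @return a multi-model [structure3d()].
#' @export
make_toy_ensemble <- function(base, n_frames, sigma = 0.3, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  xyz <- model_coords(base, 1)
  .with_seed(seed, {
    models <- lapply(seq_len(n_frames), function(f)
      xyz + matrix(stats::rnorm(length(xyz), 0, sigma), nrow(xyz), 3))
    structure3d(base$atoms, models = models, annotations = base$annotations)
  })
}
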