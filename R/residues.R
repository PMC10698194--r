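# Coarse side-chain model: beyond CB, each identity carries at most two
# pseudo-atoms (a CG-like atom and a terminal functional-group atom) placed on
# a chi grid. Radii/charges/polarity are a declared minimal table for the
# simplified score function; the terminal pseudo-atom of aromatic identities
# is inflated to stand in for the ring.

.sc_row <- function(name, element, bond, radius, charge, donor, acceptor) {
  data.frame(name = name, element = element, bond = bond, radius = radius,
             charge = charge, donor = donor, acceptor = acceptor,
             stringsAsFactors = FALSE)
}

.residue_params <- list(
  ALA = NULL,
  SER = .sc_row("OG",  "O", 1.42, 1.52, -0.40, TRUE,  TRUE),
  THR = .sc_row("OG1", "O", 1.43, 1.52, -0.40, TRUE,  TRUE),
  VAL = .sc_row("CG",  "C", 1.52, 1.90, 0.00, FALSE, FALSE),
  LEU = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("CD", "C", 1.52, 1.90, 0, FALSE, FALSE)),
  ILE = rbind(.sc_row("CG1", "C", 1.52, 1.90, 0, FALSE, FALSE),
              .sc_row("CD1", "C", 1.52, 1.70, 0, FALSE, FALSE)),
  MET = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("SD", "S", 1.80, 1.80, -0.10, FALSE, FALSE)),
  PHE = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("CZ", "C", 2.40, 2.10, 0, FALSE, FALSE)),
  TYR = rbind(.sc_row("CG", "C", 1.52, 2.10, 0, FALSE, FALSE),
              .sc_row("OH", "O", 2.80, 1.52, -0.40, TRUE, TRUE)),
  TRP = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("CZ", "C", 2.60, 2.40, 0, FALSE, FALSE)),
  ASP = rbind(.sc_row("CG", "C", 1.52, 1.70, 0.30, FALSE, FALSE),
              .sc_row("OD", "O", 1.25, 1.52, -0.80, FALSE, TRUE)),
  GLU = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("OE", "O", 2.40, 1.52, -0.80, FALSE, TRUE)),
  ASN = rbind(.sc_row("CG", "C", 1.52, 1.70, 0.30, FALSE, FALSE),
              .sc_row("OD1", "O", 1.25, 1.52, -0.55, TRUE, TRUE)),
  GLN = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("OE1", "O", 2.40, 1.52, -0.55, TRUE, TRUE)),
  HIS = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("NE2", "N", 2.20, 1.55, -0.30, TRUE, TRUE)),
  LYS = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("NZ", "N", 2.90, 1.55, 0.80, TRUE, FALSE)),
  ARG = rbind(.sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
              .sc_row("NH", "N", 3.40, 1.55, 0.80, TRUE, FALSE)),
  PRO = .sc_row("CG", "C", 1.52, 1.70, 0, FALSE, FALSE),
  GLY = NULL,
  CYS = .sc_row("SG", "S", 1.81, 1.80, -0.10, FALSE, FALSE)
)

#' Identities available for sequence design
#'
#' The 18 proteinogenic identities used during extension and design: all 20
#' amino acids excluding glycine (no side chain to design) and cysteine
#' (reserved for the thioether bridge).
#'
#' @return character vector of three-letter codes.
#' @export
designable_identities <- function() {
  setdiff(names(.residue_params), c("GLY", "CYS"))
}

#' Coarse rotamer set for an identity
#'
#' Chi angles on a -60/60/180 grid: chi1 alone for one-pseudo-atom side
#' chains, (chi1, chi2) for two, capped at 9 rotamers per identity. D
#' identities use the sign-mirrored chi grid.
#'
#' @param identity three-letter code.
#' @param chirality "L" or "D".
#' @return data.frame with columns `chi1`, `chi2` (NA when absent), one row
#'   per rotamer; zero-column case for ALA/GLY collapses to one null rotamer.
#' @export
rotamer_set <- function(identity, chirality = "L") {
  par <- .residue_params[[identity]]
  if (is.null(identity) || !identity %in% names(.residue_params))
    stop("unknown identity: ", identity)
  grid <- c(-60, 60, 180)
  if (chirality == "D") grid <- c(60, -60, 180)
  if (is.null(par)) {
    rot <- data.frame(chi1 = NA_real_, chi2 = NA_real_)
  } else if (nrow(par) == 1) {
    rot <- data.frame(chi1 = grid, chi2 = NA_real_)
  } else {
    rot <- expand.grid(chi1 = grid, chi2 = grid)
  }
  rot[seq_len(min(nrow(rot), 9L)), , drop = FALSE]
}

# Build side-chain pseudo-atom coordinates for a residue given backbone
# N/CA/CB positions and a rotamer row. Returns data.frame (possibly 0-row).
.build_sidechain <- function(identity, n_xyz, ca_xyz, cb_xyz, rotamer) {
  par <- .residue_params[[identity]]
  if (is.null(par)) return(NULL)
  out <- par
  g1 <- place_atom(n_xyz, ca_xyz, cb_xyz, par$bond[1], 114,
                   if (is.na(rotamer$chi1)) 180 else rotamer$chi1)
  xyz <- matrix(g1, nrow = 1)
  if (nrow(par) > 1) {
    g2 <- place_atom(ca_xyz, cb_xyz, g1, par$bond[2], 114,
                     if (is.na(rotamer$chi2)) 180 else rotamer$chi2)
    xyz <- rbind(xyz, g2)
  }
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}
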