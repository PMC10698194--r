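# Ensemble validation statistics: contact fractions, H-bond detection,
# C-alpha distance tables, and k-means RMSD clustering of ligand poses.

#' Hydrogen-bond criterion
#'
#' Heavy-atom acceptor-to-donor distance and angle thresholds. Angle vertex
#' convention: with `vertex = "hydrogen"` (default), donor-H-acceptor >= 135
#' degrees whenever the donor carries an explicit hydrogen; donors without
#' hydrogens fall back to the antecedent-heavy-atom-donor-acceptor angle.
#' `vertex = "antecedent"` forces the heavy-atom convention throughout.
#'
#' @param max_distance donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param min_angle angle threshold, degrees (default 135).
#' @param vertex `"hydrogen"` or `"antecedent"`.
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_distance = 3.5, min_angle = 135,
                            vertex = c("hydrogen", "antecedent")) {
  vertex <- match.arg(vertex)
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 vertex = vertex), class = "hbond_criterion")
}

#' Hydrogen-bond pairs of a model
#'
#' Enumerates (donor atom, acceptor atom) index pairs satisfying the
#' criterion. Pairs within one residue are skipped.
#'
#' @param model anything [as_energy_atoms()] accepts.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with `donor`, `acceptor` atom row indices and
#'   `distance`, `angle`.
#' @export
hbond_pairs <- function(model, criterion = hbond_criterion()) {
  at <- as_energy_atoms(model)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ish <- toupper(at$element) == "H"
  don <- which(at$donor & !ish)
  acc <- which(at$acceptor & !ish)
  res <- list()
  for (i in don) {
    js <- acc[acc != i]
    js <- js[!(at$group[js] == at$group[i] & at$res_idx[js] == at$res_idx[i])]
    if (!length(js)) next
    dv <- sweep(xyz[js, , drop = FALSE], 2, xyz[i, ])
    d <- sqrt(rowSums(dv^2))
    keep <- d <= criterion$max_distance
    js <- js[keep]; d <- d[keep]
    if (!length(js)) next
    hx <- as.numeric(at[i, c("h_x", "h_y", "h_z")])
    ax <- as.numeric(at[i, c("ant_x", "ant_y", "ant_z")])
    use_h <- criterion$vertex == "hydrogen" && all(is.finite(hx))
    if (!use_h && any(!is.finite(ax))) next
    for (k in seq_along(js)) {
      ang <- if (use_h) bond_angle(xyz[i, ], hx, xyz[js[k], ])
             else bond_angle(ax, xyz[i, ], xyz[js[k], ])
      if (ang >= criterion$min_angle)
        res[[length(res) + 1]] <- data.frame(donor = i, acceptor = js[k],
                                             distance = d[k], angle = ang)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ligand contact specification
#'
#' @param cutoff heavy-atom contact cutoff, Angstrom (default 4.5,
#'   inclusive).
#' @param ligand ligand selection: a chain name, an annotation name, or a
#'   logical vector over atoms.
#' @return object of class `contact_spec`.
#' @export
contact_spec <- function(cutoff = 4.5, ligand = "B") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, ligand = ligand), class = "contact_spec")
}

.ligand_mask <- function(x, ligand) {
  at <- x$atoms
  if (is.logical(ligand)) {
    if (length(ligand) != nrow(at)) stop("logical ligand mask length mismatch")
    return(ligand)
  }
  if (ligand %in% names(x$annotations)) return(annotation_atoms(x, ligand))
  m <- at$chain == ligand
  if (!any(m)) stop("empty ligand selection: ", ligand)
  m
}

#' Per-residue ligand contact fractions over an ensemble
#'
#' A receptor residue is in contact in a frame when any of its heavy atoms
#' lies within the cutoff (inclusive) of any ligand heavy atom; the profile
#' is the fraction of frames in contact, per residue.
#'
#' @param ensemble a multi-model [structure3d()] (frames share topology).
#' @param spec a [contact_spec()].
#' @return data.frame with `residue` (key), `resname`, `fraction`, of class
#'   `contact_profile`.
#' @export
contact_fraction <- function(ensemble, spec = contact_spec()) {
  at <- ensemble$atoms
  lig <- .ligand_mask(ensemble, spec$ligand)
  heavy <- toupper(at$element) != "H"
  li <- which(lig & heavy)
  if (!length(li)) stop("empty ligand selection (no heavy atoms)")
  ri <- which(!lig & heavy)
  keys <- residue_key(at$chain, at$resno, at$insert)
  rkeys <- keys[ri]
  ukeys <- unique(rkeys)
  nfr <- n_models(ensemble)
  hits <- matrix(0L, length(ukeys), nfr)
  for (f in seq_len(nfr)) {
    xyz <- model_coords(ensemble, f)
    A <- xyz[ri, , drop = FALSE]; B <- xyz[li, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    dmin <- sqrt(pmax(apply(d2, 1, min), 0))
    close <- tapply(dmin <= spec$cutoff, rkeys, any)
    hits[, f] <- as.integer(close[ukeys])
  }
  out <- data.frame(residue = ukeys,
                    resname = at$resname[ri][match(ukeys, rkeys)],
                    fraction = rowMeans(hits))
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Ensemble vs reference C-alpha distance table
#'
#' For each requested residue pair: mean and population standard deviation of
#' the C-alpha distance over ensemble frames, the reference-model distance,
#' and the absolute difference of means.
#'
#' @param ensemble a multi-model [structure3d()].
#' @param reference a single-model [structure3d()] (matching residue keys).
#' @param pairs data.frame with columns `res1`, `res2` holding residue keys
#'   (see [residue_key()]).
#' @return data.frame with `res1`, `res2`, `mean`, `sd`, `reference`,
#'   `abs_diff`.
#' @export
ca_distance_table <- function(ensemble, reference, pairs) {
  ca_idx <- function(x, key) {
    at <- x$atoms
    keys <- residue_key(at$chain, at$resno, at$insert)
    i <- which(keys == key & at$name == "CA")
    if (!length(i)) stop("residue has no CA or is absent: ", key)
    i[1]
  }
  nfr <- n_models(ensemble)
  out <- lapply(seq_len(nrow(pairs)), function(p) {
    i1 <- ca_idx(ensemble, pairs$res1[p]); i2 <- ca_idx(ensemble, pairs$res2[p])
    dists <- vapply(seq_len(nfr), function(f) {
      m <- model_coords(ensemble, f)
      sqrt(sum((m[i1, ] - m[i2, ])^2))
    }, 0)
    r1 <- ca_idx(reference, pairs$res1[p]); r2 <- ca_idx(reference, pairs$res2[p])
    mr <- model_coords(reference, 1)
    dref <- sqrt(sum((mr[r1, ] - mr[r2, ])^2))
    data.frame(res1 = pairs$res1[p], res2 = pairs$res2[p],
               mean = mean(dists),
               sd = sqrt(mean((dists - mean(dists))^2)),  # population sd
               reference = dref, abs_diff = abs(mean(dists) - dref))
  })
  do.call(rbind, out)
}

#' k-means clustering of ligand poses by heavy-atom coordinates
#'
#' Clusters ensemble frames on the flattened ligand heavy-atom coordinates
#' (frames are assumed pre-superposed on the receptor), keeping the best of
#' `n_init` restarts by within-cluster sum of squares. The representative is
#' the frame minimizing RMSD to the largest cluster's centroid.
#'
#' @param ensemble a multi-model [structure3d()].
#' @param ligand ligand selection (chain, annotation or logical mask).
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @param n_init random restarts (default 10).
#' @return list with `labels` (per frame), `representative` (frame index),
#'   `inertia`, `sizes`.
#' @export
kmeans_rmsd <- function(ensemble, ligand = "B", k = 2L, seed = 1L,
                        n_init = 10L) {
  nfr <- n_models(ensemble)
  if (k > nfr) stop("k exceeds number of frames")
  lig <- .ligand_mask(ensemble, ligand)
  heavy <- toupper(ensemble$atoms$element) != "H"
  li <- which(lig & heavy)
  if (!length(li)) stop("empty ligand selection")
  X <- t(vapply(seq_len(nfr), function(f)
    as.vector(t(model_coords(ensemble, f)[li, , drop = FALSE])),
    numeric(3 * length(li))))
  .with_seed(seed, {
    km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)
    big <- which.max(km$size)
    members <- which(km$cluster == big)
    cen <- km$centers[big, ]
    rms <- vapply(members, function(f)
      sqrt(mean((X[f, ] - cen)^2) * 3), 0)
    list(labels = km$cluster, representative = members[which.min(rms)],
         inertia = km$tot.withinss, sizes = km$size)
  })
}
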