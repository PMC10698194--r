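# Interface metric vector for design filtering, plus the pocket-volume tool.

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.partner_split <- function(model) {
  at <- as_energy_atoms(if (inherits(model, "conjugate_model")) model$atoms else model)
  if (!"group" %in% names(at) || length(unique(at$group)) < 2)
    stop("model is not separable into receptor and conjugate partners")
  rec <- at$group == "receptor"
  con <- !rec
  if (!any(rec) || !any(con)) stop("partner selection empty")
  list(at = at, receptor = which(rec), conjugate = which(con))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by spherical quadrature: test points on each atom's
#' solvent-expanded sphere (radius + probe), counted when not inside any
#' neighbour's expanded sphere. Hydrogens are ignored (heavy-atom radii
#' subsume them).
#'
#' @param x anything [as_energy_atoms()] accepts.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points quadrature points per atom (default 240; less than
#'   32 is refused as too coarse).
#' @return numeric vector of per-atom areas (0 for hydrogens), Angstrom^2,
#'   with attribute `total`.
#' @export
sasa <- function(x, probe = 1.4, n_sphere_points = 240L) {
  if (n_sphere_points < 32) stop("n_sphere_points < 32: quadrature too coarse")
  at <- as_energy_atoms(x)
  heavy <- which(toupper(at$element) != "H")
  out <- numeric(nrow(at))
  if (!length(heavy)) return(structure(out, total = 0))
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  R <- at$radius[heavy] + probe
  sph <- .fibonacci_sphere(n_sphere_points)
  n <- length(heavy)
  d <- as.matrix(stats::dist(xyz))
  for (k in seq_len(n)) {
    nb <- which(d[k, ] < R[k] + R & seq_len(n) != k)
    pts <- sweep(sph * R[k], 2, xyz[k, ], "+")
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      dv <- sweep(pts, 2, xyz[j, ])
      free <- free & (rowSums(dv * dv) > R[j]^2)
      if (!any(free)) break
    }
    out[heavy[k]] <- 4 * pi * R[k]^2 * sum(free) / n_sphere_points
  }
  structure(out, total = sum(out))
}

#' Interface area (buried SASA) of a conjugate model
#'
#' `dSASA = SASA(receptor alone) + SASA(conjugate alone) - SASA(complex)`,
#' reported un-halved.
#'
#' @param model a `conjugate_model` (or energy atom table with a `group`
#'   column separating "receptor" from the rest).
#' @param probe,n_sphere_points passed to [sasa()].
#' @return buried area, Angstrom^2.
#' @export
interface_area <- function(model, probe = 1.4, n_sphere_points = 240L) {
  sp <- .partner_split(model)
  s_all <- attr(sasa(sp$at, probe, n_sphere_points), "total")
  s_rec <- attr(sasa(sp$at[sp$receptor, ], probe, n_sphere_points), "total")
  s_con <- attr(sasa(sp$at[sp$conjugate, ], probe, n_sphere_points), "total")
  s_rec + s_con - s_all
}

#' Binding energy difference of a conjugate model
#'
#' `total_energy(complex) - total_energy(receptor alone) -
#' total_energy(conjugate alone)` under rigid separation (no repacking).
#'
#' @param model a `conjugate_model` or grouped energy atom table.
#' @param weights an [energy_weights()].
#' @return energy difference, arbitrary units (negative favours binding).
#' @export
ddg <- function(model, weights = energy_weights()) {
  sp <- .partner_split(model)
  total_energy(sp$at, weights) -
    total_energy(sp$at[sp$receptor, ], weights) -
    total_energy(sp$at[sp$conjugate, ], weights)
}

# surface dots (vdW surface) with outward radial normals and area weights;
# occlusion is tested against neighbour atoms only
.surface_dots <- function(at, density = 5) {
  heavy <- which(toupper(at$element) != "H")
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  r <- at$radius[heavy]
  nheavy <- length(heavy)
  dmat <- as.matrix(stats::dist(xyz))
  dots <- list(); normals <- list(); areas <- list()
  for (k in seq_len(nheavy)) {
    npt <- max(12L, round(density * 4 * pi * r[k]^2))
    sph <- .fibonacci_sphere(npt)
    pts <- sweep(sph * r[k], 2, xyz[k, ], "+")
    free <- rep(TRUE, npt)
    for (j in which(dmat[k, ] < r + r[k] & seq_len(nheavy) != k)) {
      dv <- sweep(pts, 2, xyz[j, ])
      free <- free & (rowSums(dv * dv) > r[j]^2)
      if (!any(free)) break
    }
    if (!any(free)) next
    dots[[length(dots) + 1]] <- pts[free, , drop = FALSE]
    normals[[length(normals) + 1]] <- sph[free, , drop = FALSE]
    areas[[length(areas) + 1]] <- rep(4 * pi * r[k]^2 / npt, sum(free))
  }
  list(dots = do.call(rbind, dots), normals = do.call(rbind, normals),
       areas = unlist(areas))
}

.nearest_dot <- function(A, B, chunk = 512L) {
  # for each row of A: index and distance of nearest row of B (chunked to
  # bound memory)
  nA <- nrow(A)
  b2 <- rowSums(B^2)
  idx <- integer(nA); dst <- numeric(nA)
  for (s in seq(1, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), rep(1, nrow(B))) +
          outer(rep(1, nrow(Ab)), b2) - 2 * Ab %*% t(B)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(Ab)), j)], 0))
  }
  list(idx = idx, dist = dst)
}

# atoms of each partner within `reach` of the other partner (interface zone)
.interface_atoms <- function(at, ia, ib, reach = 8) {
  A <- as.matrix(at[ia, c("x", "y", "z")])
  B <- as.matrix(at[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2 <- pmax(d2, 0)
  list(a = ia[sqrt(apply(d2, 1, min)) <= reach],
       b = ib[sqrt(apply(d2, 2, min)) <= reach])
}

#' Shape-complementarity statistic from two dot surfaces
#'
#' The Lawrence-Colman statistic on explicit dot clouds: for each
#' interface-zone dot (nearest partner dot within `trim_distance`), the local
#' score is `(n_a . -n_b) * exp(-w * d^2)`; the statistic is the mean of the
#' two directional medians.
#'
#' @param dots_a,dots_b n x 3 dot coordinate matrices.
#' @param normals_a,normals_b matching outward unit normals.
#' @param w Gaussian distance weight, 1/Angstrom^2 (default 0.5).
#' @param trim_distance interface-zone cutoff, Angstrom (default 1.5).
#' @return list with `sc`, `n_a`, `n_b` (zone dot counts per side).
#' @export
sc_from_dots <- function(dots_a, normals_a, dots_b, normals_b,
                         w = 0.5, trim_distance = 1.5) {
  half <- function(A, NA_, B, NB) {
    nn <- .nearest_dot(A, B)
    zone <- nn$dist <= trim_distance
    if (!any(zone)) return(list(med = NA_real_, n = 0L))
    s <- rowSums(NA_[zone, , drop = FALSE] * -NB[nn$idx[zone], , drop = FALSE]) *
      exp(-w * nn$dist[zone]^2)
    list(med = stats::median(s), n = sum(zone))
  }
  ab <- half(dots_a, normals_a, dots_b, normals_b)
  ba <- half(dots_b, normals_b, dots_a, normals_a)
  if (ab$n == 0L || ba$n == 0L)
    stop("no interface-zone dots: partners too far apart")
  list(sc = mean(c(ab$med, ba$med)), n_a = ab$n, n_b = ba$n)
}

#' Shape complementarity of a conjugate interface
#'
#' Generates van-der-Waals surface dots with outward normals for receptor and
#' conjugate partners (default density 5 dots per Angstrom^2) and evaluates
#' [sc_from_dots()]. Values lie in [-1, 1]; 1 is a perfect fit.
#'
#' @param model a `conjugate_model` or grouped energy atom table.
#' @param trim_distance interface-zone cutoff, Angstrom.
#' @param w Gaussian distance weight, 1/Angstrom^2.
#' @param density surface dot density, dots per Angstrom^2.
#' @return shape complementarity, dimensionless.
#' @export
shape_complementarity <- function(model, trim_distance = 1.5, w = 0.5,
                                  density = 5) {
  sp <- .partner_split(model)
  iz <- .interface_atoms(sp$at, sp$receptor, sp$conjugate)
  if (!length(iz$a) || !length(iz$b))
    stop("no interface-zone dots: partners too far apart")
  sa <- .surface_dots(sp$at[iz$a, ], density)
  sb <- .surface_dots(sp$at[iz$b, ], density)
  if (is.null(sa$dots) || is.null(sb$dots))
    stop("no surface dots for one partner")
  sc_from_dots(sa$dots, sa$normals, sb$dots, sb$normals,
               w = w, trim_distance = trim_distance)$sc
}

#' Contact molecular surface of the conjugate
#'
#' Area-weighted sum of conjugate surface dots whose nearest receptor surface
#' dot lies within `contact_distance`. Monotone non-decreasing in
#' `contact_distance`.
#'
#' @param model a `conjugate_model` or grouped energy atom table.
#' @param contact_distance Angstrom (default 1.5).
#' @param density surface dot density, dots per Angstrom^2.
#' @return contact area, Angstrom^2.
#' @export
contact_molecular_surface <- function(model, contact_distance = 1.5,
                                      density = 5) {
  sp <- .partner_split(model)
  iz <- .interface_atoms(sp$at, sp$receptor, sp$conjugate)
  if (!length(iz$a) || !length(iz$b)) return(0)
  sa <- .surface_dots(sp$at[iz$a, ], density)
  sb <- .surface_dots(sp$at[iz$b, ], density)
  if (is.null(sa$dots) || is.null(sb$dots)) return(0)
  nn <- .nearest_dot(sb$dots, sa$dots)
  sum(sb$areas[nn$dist <= contact_distance])
}

#' Buried unsatisfied polar atoms
#'
#' Counts polar (donor or acceptor) heavy atoms that are buried (per-atom
#' SASA below `sasa_threshold`) yet have no hydrogen-bond partner under the
#' shared criterion.
#'
#' @param model a `conjugate_model` or energy atom table.
#' @param sasa_threshold burial threshold, Angstrom^2 (default 0.01).
#' @param criterion an [hbond_criterion()].
#' @param probe,n_sphere_points passed to [sasa()].
#' @return integer count.
#' @export
buried_unsats <- function(model, sasa_threshold = 0.01,
                          criterion = hbond_criterion(), probe = 1.4,
                          n_sphere_points = 240L) {
  at <- as_energy_atoms(if (inherits(model, "conjugate_model")) model$atoms else model)
  a <- sasa(at, probe, n_sphere_points)
  polar <- which((at$donor | at$acceptor) & toupper(at$element) != "H")
  buried <- polar[a[polar] < sasa_threshold]
  if (!length(buried)) return(0L)
  hp <- hbond_pairs(at, criterion)
  satisfied <- unique(c(hp$donor, hp$acceptor))
  sum(!(buried %in% satisfied))
}

#' Full interface metric vector of one design
#'
#' The filter vector used by the design funnel: total score, binding energy
#' difference, shape complementarity, interface area, contact molecular
#' surface and buried unsatisfied polars.
#'
#' @param model a `conjugate_model`.
#' @param weights an [energy_weights()].
#' @param n_sphere_points SASA quadrature (default 120 here: the funnel ranks
#'   hundreds of designs and percentile cuts tolerate modest quadrature).
#' @return one-row data.frame of class `interface_metrics`.
#' @export
interface_metrics <- function(model, weights = energy_weights(),
                              n_sphere_points = 120L) {
  out <- data.frame(
    total_score = total_energy(model$atoms, weights),
    ddg = ddg(model, weights),
    sc = tryCatch(shape_complementarity(model), error = function(e) NA_real_),
    interface_area = interface_area(model, n_sphere_points = n_sphere_points),
    cms = contact_molecular_surface(model),
    buried_unsats = buried_unsats(model, n_sphere_points = n_sphere_points))
  class(out) <- c("interface_metrics", "data.frame")
  out
}

#' Pocket volume by grid flood fill
#'
#' Probe-accessible cavity volume: a grid cell is free when its centre lies
#' at least `radius + probe` from every atom centre; the pocket is the
#' flood-filled free region containing `seed_point` (6-connectivity). A flood
#' that reaches the bounding-box shell means the pocket is open to bulk: the
#' volume is then capped at the visited cells and a warning is raised.
#'
#' @param receptor a [structure3d()] or energy atom table.
#' @param seed_point numeric 3-vector inside the cavity.
#' @param grid grid spacing, Angstrom (default 0.5).
#' @param probe probe radius, Angstrom (default 1.4).
#' @return object of class `pocket_measurement`: `volume` (Angstrom^3),
#'   `n_cells`, `grid`, `open`.
#' @export
pocket_volume <- function(receptor, seed_point, grid = 0.5, probe = 1.4) {
  at <- as_energy_atoms(receptor)
  heavy <- toupper(at$element) != "H"
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  rad <- at$radius[heavy] + probe
  dmin <- sqrt(colSums((t(xyz) - seed_point)^2))
  if (any(dmin < at$radius[heavy]))
    stop("seed point lies inside an atom")
  lo <- apply(xyz, 2, min) - max(rad) - grid
  hi <- apply(xyz, 2, max) + max(rad) + grid
  nx <- ceiling((hi - lo) / grid) + 1L
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(nx[k]) - 1) * grid)
  # free mask: cell centre further than radius+probe from every atom centre
  free <- array(TRUE, dim = nx)
  gx <- ax[[1]]; gy <- ax[[2]]; gz <- ax[[3]]
  for (a in seq_len(nrow(xyz))) {
    r <- rad[a]
    ix <- which(abs(gx - xyz[a, 1]) <= r)
    iy <- which(abs(gy - xyz[a, 2]) <= r)
    iz <- which(abs(gz - xyz[a, 3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[a, 1])^2
    dy2 <- (gy[iy] - xyz[a, 2])^2
    dz2 <- (gz[iz] - xyz[a, 3])^2
    blk <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    free[ix, iy, iz] <- free[ix, iy, iz] & !blk
  }
  s <- pmin(pmax(round((seed_point - lo) / grid) + 1L, 1L), nx)
  if (!free[s[1], s[2], s[3]])
    stop("seed point is not probe-accessible on this grid")
  # BFS flood fill, 6-connectivity
  visited <- array(FALSE, dim = nx)
  queue <- matrix(s, ncol = 3)
  visited[s[1], s[2], s[3]] <- TRUE
  open_pocket <- FALSE
  steps <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (nrow(queue)) {
    nxt <- list()
    for (q in seq_len(nrow(queue))) {
      c0 <- queue[q, ]
      for (st in seq_len(6)) {
        cc <- c0 + steps[st, ]
        if (any(cc < 1L) || any(cc > nx)) next
        if (visited[cc[1], cc[2], cc[3]] || !free[cc[1], cc[2], cc[3]]) next
        if (any(cc == 1L) || any(cc == nx)) open_pocket <- TRUE
        visited[cc[1], cc[2], cc[3]] <- TRUE
        nxt[[length(nxt) + 1]] <- cc
      }
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else matrix(numeric(), ncol = 3)
  }
  n_cells <- sum(visited)
  if (open_pocket)
    warning("pocket is open to bulk solvent; volume capped at visited cells")
  structure(list(volume = n_cells * grid^3, n_cells = n_cells, grid = grid,
                 seed_point = seed_point, open = open_pocket),
            class = "pocket_measurement")
}

#' @export
print.pocket_measurement <- function(x, ...) {
  cat(sprintf("pocket_measurement: %.1f A^3 (%d cells at %.2f A grid)%s\n",
              x$volume, x$n_cells, x$grid,
              if (x$open) " [open to bulk]" else ""))
  invisible(x)
}
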