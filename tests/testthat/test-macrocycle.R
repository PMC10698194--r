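test_that("sample_backbones is deterministic and every macrocycle passes
           independent closure re-measurement", {
  lib <- small_library()
  lib2 <- sample_backbones(6, 12, seed = 101)
  expect_identical(lapply(lib, function(b) b$atoms),
                   lapply(lib2, function(b) b$atoms))
  for (b in lib) {
    at <- b$atoms
    g <- function(ri, nm)
      as.numeric(at[at$res_idx == ri & at$name == nm, c("x", "y", "z")])
    # re-measure from coordinates, not from the sampler's bookkeeping
    d <- sqrt(sum((g(6, "SG") - g(0, "CM"))^2))
    v1 <- g(6, "CB") - g(6, "SG"); v2 <- g(0, "CM") - g(6, "SG")
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_lte(abs(d - 1.81), 0.2)
    expect_lte(abs(ang - 100), 15)
    # built bridge bonds are at ideal geometry
    expect_equal(sqrt(sum((g(0, "CM") - g(0, "CL"))^2)), 1.52, tolerance = 1e-6)
    expect_equal(sqrt(sum((g(0, "CL") - g(1, "N"))^2)), 1.33, tolerance = 1e-6)
  }
  expect_error(sample_backbones(3, 10, seed = 1), "ring_size")
  expect_error(sample_backbones(6, 0, seed = 1), "n_samples")
})

test_that("close_ring is a fixed point on closed rings and reports failure
           as a value on infeasible chains", {
  b <- small_library()[[1]]
  again <- close_ring(b)
  expect_true(again$closure$success)
  expect_identical(again$closure$iterations, 0L)
  expect_identical(again$atoms, b$atoms)

  # perturb the last residue's torsions to open a gap, then re-close
  open_bb <- peptide_backbone(b$residues$phi + c(0, 0, 0, 0, 25, 40),
                              b$residues$psi + c(0, 0, 0, 0, -30, 35),
                              b$residues$omega,
                              chirality = b$residues$chirality)
  expect_false(closure_residuals(open_bb)$ok)
  closed <- close_ring(open_bb)
  if (closed$closure$success) {
    cr <- closure_residuals(closed)
    expect_true(cr$ok)
  }

  # fully extended chain: ends tens of Angstrom apart, middle torsions frozen
  far <- peptide_backbone(rep(-179, 8), rep(179, 8), rep(180, 8))
  expect_gt(closure_residuals(far)$bond, 20)
  res <- close_ring(far)
  expect_false(res$closure$success)
  expect_true(is.finite(res$closure$bond))
  expect_true(is.finite(res$closure$angle))
})

test_that("torsion bins match the declared partition on the spec examples and
           random triples", {
  expect_equal(torsion_bin(-60, -45, 180), "A")
  expect_equal(torsion_bin(-120, 130, 180), "B")
  expect_equal(torsion_bin(60, 40, 0), "O")   # cis rule takes precedence
  expect_equal(torsion_bin(60, 40, 180), "G")
  expect_equal(torsion_bin(60, 120, 180), "E")
  # independent oracle re-stating the bin definitions
  oracle <- function(phi, psi, om) {
    if (abs(om) < 90) return("O")
    if (phi == 180) phi <- -180
    if (phi < 0) {
      if (psi >= -75 && psi < 50) "A" else "B"
    } else {
      if (psi >= -100 && psi < 100) "G" else "E"
    }
  }
  set.seed(77)
  phi <- runif(10000, -180, 180); psi <- runif(10000, -180, 180)
  om <- runif(10000, -180, 180)
  got <- torsion_bin(phi, psi, om)
  want <- mapply(oracle, phi, psi, om)
  expect_identical(got, unname(want))
  # the five bins partition the torus: every triple gets exactly one label
  expect_true(all(got %in% c("A", "B", "G", "E", "O")))
  expect_error(torsion_bin(NA, 0, 180), "undefined")
})

test_that("hbond_fingerprint applies the shared criterion to backbone N-H...O", {
  # hand-built five-residue scaffold: residue 5's N-H donates to residue 1's O
  mk <- function(with_pair = TRUE, dist = 2.9, ang = 165) {
    rows <- list()
    add <- function(ri, nm, el, p)
      rows[[length(rows) + 1]] <<- data.frame(res_idx = ri, name = nm,
                                              element = el, x = p[1],
                                              y = p[2], z = p[3])
    for (i in 1:5) {
      base <- c(20 * i, 0, 0)   # far apart by default
      add(i, "N", "N", base)
      add(i, "H", "H", base + c(0, 1.0, 0))
      add(i, "O", "O", base + c(5, 0, 0))
    }
    if (with_pair) {
      # rebuild residue 5's N/H and residue 1's O in H-bond geometry:
      # N at origin, H along +y, O placed at `dist` from N making the
      # requested N-H...O angle at H
      rows[[13]]$x <- 0; rows[[13]]$y <- 0; rows[[13]]$z <- 0
      rows[[14]]$x <- 0; rows[[14]]$y <- 1.0; rows[[14]]$z <- 0
      o <- hbond_O_position(dist, ang)
      rows[[3]]$x <- o[1]; rows[[3]]$y <- o[2]; rows[[3]]$z <- o[3]
    }
    at <- do.call(rbind, rows)
    bb <- structure(list(ring_size = 5L, atoms = at), class = "peptide_backbone")
    bb
  }
  bb <- mk(TRUE, 2.9, 165)
  fp <- hbond_fingerprint(bb)
  expect_equal(nrow(fp), 1L)
  expect_equal(c(fp$donor, fp$acceptor), c(5L, 1L))
  expect_equal(fingerprint_string(fp), "5>1")
  # fully separated scaffold: empty fingerprint
  expect_equal(nrow(hbond_fingerprint(mk(FALSE))), 0L)
  expect_equal(fingerprint_string(hbond_fingerprint(mk(FALSE))), "-")
  # tightening the distance threshold empties it (monotonicity)
  expect_equal(nrow(hbond_fingerprint(bb, hbond_criterion(2.0, 135))), 0L)
  # angle below threshold is excluded
  expect_equal(nrow(hbond_fingerprint(mk(TRUE, 2.9, 120))), 0L)
})

test_that("cluster_backbones groups exactly on key and picks the brute-force
           medoid", {
  lib <- small_library()
  b <- lib[[1]]
  # two identical backbones form one cluster of size 2
  cl <- cluster_backbones(list(b, b))
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members), c(1L, 2L))
  expect_true(cl[[1]]$representative %in% cl[[1]]$members)

  # clustering is a partition invariant to library order
  cl_all <- cluster_backbones(lib)
  members <- sort(unlist(lapply(cl_all, function(c) c$members)))
  expect_equal(members, seq_along(lib))
  perm <- rev(seq_along(lib))
  cl_perm <- cluster_backbones(lib[perm])
  keys <- sort(vapply(cl_all, function(c) c$key, ""))
  keys_p <- sort(vapply(cl_perm, function(c) c$key, ""))
  expect_identical(keys, keys_p)

  # a five-member cluster built by small same-bin torsion jitter:
  # medoid must equal the exhaustive min-total-RMSD member
  set.seed(9)
  fam <- lapply(1:5, function(i) {
    bb <- peptide_backbone(c(-63, -63, -120, -63, 60, -63) + runif(6, -4, 4),
                           c(-41, -41, 130, -41, 40, -41) + runif(6, -4, 4),
                           rep(180, 6))
    bb
  })
  bins <- vapply(fam, torsion_bins, "")
  expect_length(unique(bins), 1L)
  clf <- cluster_backbones(fam)
  expect_length(clf, 1L)
  dm <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    if (j > i) dm[i, j] <- dm[j, i] <- backbone_rmsd(fam[[i]], fam[[j]])
  expect_equal(clf[[1]]$representative, which.min(rowSums(dm)))

  expect_error(cluster_backbones(list()), "empty")
  b5 <- sample_backbones(5, 1, seed = 3)[[1]]
  expect_error(cluster_backbones(list(b, b5)), "mixed ring sizes")
})

test_that("library serialization writes a multi-model PDB plus sidecar table", {
  lib <- small_library()[1:4]
  pdb <- withr::local_tempfile(fileext = ".pdb")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  side <- write_backbone_library(lib, pdb, tsv)
  expect_equal(nrow(side), 4L)
  expect_true(all(c("id", "seed", "bins", "fingerprint", "closure_bond",
                    "closure_angle") %in% names(side)))
  reread <- read_pdb(pdb, model_policy = "all")
  expect_equal(n_models(reread), 4L)
  expect_equal(model_coords(reread, 2),
               as.matrix(lib[[2]]$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(tab$bins, side$bins)
})
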