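test_that("read_pdb parses records, resolves altlocs, and validates input", {
  s <- read_pdb(tiny_pdb_text())
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 5L)
  expect_equal(n_models(s), 1L)
  expect_equal(s$atoms$resno, c(1, 1, 1, 1, 10))
  expect_true(s$atoms$het[5])

  # altloc policy "first" keeps only the A conformer
  alt <- paste(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA BALA A   1      11.739   6.171  -5.247  1.00  0.00           C",
    "ATOM      4  C   ALA A   1      12.893   6.943  -5.032  1.00  0.00           C",
    "END"), collapse = "\n")
  s1 <- read_pdb(alt, altloc_policy = "first")
  expect_equal(sum(s1$atoms$name == "CA"), 1L)
  expect_equal(s1$atoms$x[s1$atoms$name == "CA"], 11.639)

  # malformed coordinate field names the line
  bad <- sub("11.104", "xx.xxx", tiny_pdb_text())
  expect_error(read_pdb(bad), "malformed coordinate field.*line 1")

  # amino-acid residue missing backbone atoms is a structural error
  noca <- paste(c(
    "ATOM      1  N   ALA A   7      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  C   ALA A   7      12.893   6.943  -5.032  1.00  0.00           C",
    "END"), collapse = "\n")
  expect_error(read_pdb(noca), "missing backbone N/CA/C.*A:7")
})

test_that("PDB write/read roundtrip preserves topology and coordinates", {
  s <- read_pdb(tiny_pdb_text())
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(model_coords(s2), model_coords(s), tolerance = 1e-3)

  # multi-model roundtrip keeps every frame
  ens <- make_toy_ensemble(s, n_frames = 3, sigma = 0.2, seed = 4)
  write_pdb(ens, path)
  ens2 <- read_pdb(path, model_policy = "all")
  expect_equal(n_models(ens2), 3L)
  for (f in 1:3)
    expect_equal(model_coords(ens2, f), model_coords(ens, f), tolerance = 1e-3)
})

test_that("dihedral follows the IUPAC sign convention and rejects degeneracy", {
  # cis arrangement: p1 and p4 eclipsed
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # trans arrangement
  expect_equal(abs(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))),
               180)
  # hand-worked right angle, positive sign
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  # invariant under full path reversal; antisymmetric under mirror reflection
  set.seed(31)
  mirror <- function(v) v * c(1, 1, -1)
  for (i in 1:10) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    d <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(d, dihedral(p[[4]], p[[3]], p[[2]], p[[1]]),
                 tolerance = 1e-9)
    expect_equal(dihedral(mirror(p[[1]]), mirror(p[[2]]), mirror(p[[3]]),
                          mirror(p[[4]])), -d, tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "colinear")
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
})

test_that("place_atom reproduces the requested internal coordinates", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(3); b <- a + rnorm(3); c <- b + rnorm(3)
    len <- runif(1, 1, 2); ang <- runif(1, 60, 150); tor <- runif(1, -179, 179)
    d <- place_atom(a, b, c, len, ang, tor)
    expect_equal(sqrt(sum((d - c)^2)), len, tolerance = 1e-9)
    expect_equal(bond_angle(b, c, d), ang, tolerance = 1e-9)
    expect_equal(dihedral(a, b, c, d), tor, tolerance = 1e-9)
  }
})

test_that("kabsch recovers rigid motions and refuses reflections", {
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  # identity
  fit <- kabsch(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  # pure translation
  fit <- kabsch(X, sweep(X, 2, c(5, 0, 0), "+"))
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(5, 0, 0), tolerance = 1e-9)
  # chiral 4-point set vs its mirror image: residual RMSD > 0, and the value
  # matches an independent rotation-grid + refinement search
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0, 0, 1.0))
  M <- P %*% diag(c(1, 1, -1))
  fit <- kabsch(M, P)
  expect_gt(fit$rmsd, 0.1)
  rot_z <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  rot_y <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rms_for <- function(ang) {
    R <- rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])
    A <- sweep(M, 2, colMeans(M))
    B <- sweep(P, 2, colMeans(P))
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, by = pi / 18),
                                b = seq(0, pi, by = pi / 18),
                                c = seq(0, 2 * pi, by = pi / 18)))
  vals <- apply(grid, 1, rms_for)
  best <- stats::optim(grid[which.min(vals), ], rms_for,
                       control = list(reltol = 1e-14))
  expect_equal(fit$rmsd, best$value, tolerance = 1e-4)

  expect_error(kabsch(X[1:2, ], X[1:2, ]), "at least 3")
  colin <- cbind(1:4, 0, 0)
  expect_warning(kabsch(colin, colin), "degenerate")
})

test_that("superposition RMSD is invariant under rigid pre-transformation", {
  set.seed(23)
  X <- matrix(rnorm(24), 8, 3)
  Y <- X + matrix(rnorm(24, 0, 0.3), 8, 3)
  base <- kabsch(X, Y)$rmsd
  for (i in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    Xr <- sweep(X %*% t(R), 2, rnorm(3, 0, 10), "+")
    expect_equal(kabsch(Xr, Y)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("rigid_transform validates orthonormality and annotations resolve", {
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3), c(0, 0, 0)),
               "orthonormal|proper")
  s <- read_pdb(tiny_pdb_text())
  s2 <- structure3d(s$atoms, annotations = list(lig = "B:10"))
  expect_equal(sum(annotation_atoms(s2, "lig")), 1L)
  expect_error(structure3d(s$atoms, annotations = list(bad = "Z:99")),
               "absent residues")
})
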