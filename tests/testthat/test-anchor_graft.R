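test_that("enumerate_extensions sweeps 36 identities deterministically and
           scores reduce to internal energy without a receptor", {
  an <- make_toy_anchor()
  cands <- enumerate_extensions(an, NULL, torsion_samples_per_identity = 2,
                                seed = 19)
  expect_length(cands, 36L)   # (20 - Gly - Cys) x {L, D}
  labs <- vapply(cands, function(c) c$label, "")
  expect_length(unique(labs), 36L)
  expect_false(any(grepl("GLY|CYS", labs)))
  cands2 <- enumerate_extensions(an, NULL, torsion_samples_per_identity = 2,
                                 seed = 19)
  expect_identical(vapply(cands2, function(c) c$score, 0),
                   vapply(cands, function(c) c$score, 0))
  # no receptor: the score is the extension-internal energy alone
  c1 <- cands[[1]]
  dip <- c1$atoms; dip$group <- "extension"
  expect_equal(c1$score, total_energy(as_energy_atoms(dip)), tolerance = 1e-9)
  expect_error(enumerate_extensions(an, NULL, 0, seed = 1),
               "torsion_samples_per_identity")
})

test_that("rank_extensions is an ascending, tie-stable total order", {
  mk <- function(label, score)
    structure(list(label = label, score = score), class = "extension_candidate")
  cands <- list(mk("D-PHE+L-THR", -3), mk("D-PHE+L-ALA", -5),
                mk("D-PHE+D-SER", -5), mk("D-PHE+L-GLN", -1))
  top <- rank_extensions(cands, 3)
  expect_equal(vapply(top, function(c) c$label, ""),
               c("D-PHE+D-SER", "D-PHE+L-ALA", "D-PHE+L-THR"))
  # permutation stability
  top2 <- rank_extensions(rev(cands), 3)
  expect_equal(vapply(top2, function(c) c$label, ""),
               vapply(top, function(c) c$label, ""))
  expect_warning(kept <- rank_extensions(cands, 10), "exceeds")
  expect_length(kept, 4L)
  expect_error(rank_extensions(cands, 0), "keep")
})

test_that("graft recovers rigid motions exactly and rejects distorted frames", {
  b <- small_library()[[1]]
  at <- b$atoms
  frame <- rbind(
    C = as.numeric(at[at$res_idx == 6 & at$name == "C", c("x", "y", "z")]),
    N = as.numeric(at[at$res_idx == 6 & at$name == "N", c("x", "y", "z")]),
    O = as.numeric(at[at$res_idx == 6 & at$name == "O", c("x", "y", "z")]),
    CA = as.numeric(at[at$res_idx == 6 & at$name == "CA", c("x", "y", "z")]),
    CB = as.numeric(at[at$res_idx == 6 & at$name == "CB", c("x", "y", "z")]))
  # frame equal to the backbone's own terminal frame: identity graft
  g0 <- graft(b, frame)
  expect_equal(g0$graft_rmsd, 0, tolerance = 1e-9)
  expect_equal(as.matrix(g0$atoms[, c("x", "y", "z")]),
               as.matrix(at[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # frame rotated 90 degrees about z and translated: recovered exactly,
  # and all peptide-internal distances are preserved (rigid motion)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  frame_rt <- sweep(frame %*% t(Rz), 2, c(4, -2, 7), "+")
  g1 <- graft(b, frame_rt)
  expect_s3_class(g1, "peptide_backbone")
  expect_equal(g1$graft_rmsd, 0, tolerance = 1e-6)
  d_before <- dist(as.matrix(at[, c("x", "y", "z")]))
  d_after <- dist(as.matrix(g1$atoms[, c("x", "y", "z")]))
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-6)
  # internally distorted frame: rejected, with the RMSD equal to an
  # independently computed optimal superposition residual
  frame_bad <- frame
  frame_bad["O", ] <- frame_bad["O", ] + c(2.0, 2.0, 1.5)
  frame_bad["CB", ] <- frame_bad["CB", ] - c(1.0, 0, 1.2)
  res <- graft(b, frame_bad)
  expect_s3_class(res, "graft_failure")
  expect_false(res$success)
  A <- sweep(frame, 2, colMeans(frame))
  B <- sweep(frame_bad, 2, colMeans(frame_bad))
  s <- svd(crossprod(A, B))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  expect_equal(res$rmsd, sqrt(mean(rowSums((A %*% t(R) - B)^2))),
               tolerance = 1e-9)
  expect_error(graft(b, frame[1:3, ]), "anchor_frame")
})

test_that("clash_screen counts vdW overlaps and matches brute force", {
  fake_model <- function(pep_xyz, env_xyz, radius = 1.7) {
    at <- rbind(atoms_df(pep_xyz, group = "peptide", radius = radius),
                atoms_df(env_xyz, group = "receptor", radius = radius))
    at$res_idx <- seq_len(nrow(at)) * 10L   # no shared residues, no bonds
    structure(list(atoms = at), class = "conjugate_model")
  }
  # two heavy atoms (radius 1.7) at 1.0 A: 1.0 < 3.4 - 0.4, one clash...
  # but 1.0 A would also be detected as a covalent bond, so use 2.1 A
  m <- fake_model(c(0, 0, 0), c(2.1, 0, 0))
  expect_equal(clash_screen(m)$count, 1L)
  # same pair at 3.2 A: no clash
  expect_equal(clash_screen(fake_model(c(0, 0, 0), c(3.2, 0, 0)))$count, 0L)
  # engineered fixture with exactly 6 overlaps against max_clashes = 5
  env <- rbind(c(2.2, 0, 0), c(-2.2, 0, 0), c(0, 2.2, 0),
               c(0, -2.2, 0), c(0, 0, 2.2), c(0, 0, -2.2), c(9, 9, 9))
  m6 <- fake_model(c(0, 0, 0), as.vector(t(env)))
  cs <- clash_screen(m6, max_clashes = 5)
  expect_false(cs$pass)
  expect_equal(cs$count, 6L)
  # brute-force O(n^2) oracle on a 300-atom Poisson-disk fixture (no pair
  # close enough to register as a covalent bond, so no exclusions apply)
  set.seed(55)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < 300) {
    p <- runif(3, 0, 26)
    if (!nrow(pts) || min(sqrt(rowSums(sweep(pts, 2, p)^2))) > 2.2)
      pts <- rbind(pts, p)
  }
  rad <- runif(300, 1.3, 1.9)
  grp <- rep(c("peptide", "receptor"), c(100, 200))
  at <- atoms_df(as.vector(t(pts)), radius = rad, group = grp)
  big <- structure(list(atoms = at), class = "conjugate_model")
  got <- clash_screen(big)
  brute <- 0L
  for (i in 1:100) for (j in 101:300) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d < rad[i] + rad[j] - 0.4) brute <- brute + 1L
  }
  expect_equal(got$count, brute)
})

test_that("conjugate assembly preserves the amide link geometry", {
  m <- small_conjugate()
  expect_s3_class(m, "conjugate_model")
  expect_lte(abs(m$link$length - 1.33), 0.2)
  expect_equal(sort(unique(m$atoms$group)),
               c("anchor", "peptide", "receptor"))
  expect_equal(nchar(m$peptide_bins), m$ring_size)
})
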