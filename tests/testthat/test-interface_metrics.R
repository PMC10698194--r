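test_that("sasa matches analytic sphere areas and a Monte-Carlo oracle", {
  # single atom, radius 1.9: 4*pi*(1.9+1.4)^2 within quadrature tolerance 2%
  one <- atoms_df(c(0, 0, 0), radius = 1.9)
  a1 <- attr(sasa(one), "total")
  expect_lt(abs(a1 - 4 * pi * 3.3^2) / (4 * pi * 3.3^2), 0.02)
  # two atoms 50 A apart: additivity of disjoint spheres
  two <- atoms_df(c(0, 0, 0, 50, 0, 0), radius = c(1.9, 1.6))
  expect_equal(attr(sasa(two), "total"),
               4 * pi * (3.3^2 + 3.0^2), tolerance = 0.02 * 4 * pi * 3.3^2)
  # an atom fully enclosed by a dense shell has ~0 area
  shell_pts <- 4.0 * lariatforge:::.fibonacci_sphere(120)
  shell <- atoms_df(as.vector(t(rbind(c(0, 0, 0), shell_pts))),
                    radius = c(1.7, rep(1.7, 120)))
  expect_lt(sasa(shell)[1], 1e-6)
  # quadrature floor
  expect_error(sasa(one, n_sphere_points = 16), "too coarse")
  # Monte-Carlo rejection-sampling oracle on 20 random clusters
  set.seed(131)
  mc_sasa <- function(xyz, r, probe = 1.4, npts = 4000) {
    R <- r + probe
    tot <- 0
    for (k in seq_len(nrow(xyz))) {
      u <- matrix(rnorm(3 * npts), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * R[k], 2, xyz[k, ], "+")
      free <- rep(TRUE, npts)
      for (j in seq_len(nrow(xyz))) {
        if (j == k) next
        free <- free & rowSums(sweep(pts, 2, xyz[j, ])^2) > R[j]^2
      }
      tot <- tot + 4 * pi * R[k]^2 * mean(free)
    }
    tot
  }
  for (rep_i in 1:20) {
    n <- sample(3:6, 1)
    xyz <- matrix(runif(3 * n, 0, 5), n, 3)
    r <- runif(n, 1.4, 1.9)
    at <- atoms_df(as.vector(t(xyz)), radius = r)
    got <- attr(sasa(at), "total")
    want <- mc_sasa(xyz, r)
    expect_lt(abs(got - want) / want, 0.02)
  }
})

test_that("interface area is the non-negative buried SASA of the partners", {
  # partners 50 A apart bury nothing
  far <- atoms_df(c(0, 0, 0, 50, 0, 0), radius = 1.7,
                  group = c("receptor", "conjugate"))
  expect_equal(interface_area(far), 0, tolerance = 1e-9)
  # touching spheres bury a positive area equal to the difference of totals
  near <- atoms_df(c(0, 0, 0, 3.5, 0, 0), radius = 1.7,
                   group = c("receptor", "conjugate"))
  ia <- interface_area(near)
  expect_gt(ia, 10)
  s_all <- attr(sasa(near), "total")
  s_each <- attr(sasa(atoms_df(c(0, 0, 0), radius = 1.7)), "total")
  expect_equal(ia, 2 * s_each - s_all, tolerance = 1e-9)
  # dSASA >= 0 on random two-partner fixtures
  set.seed(17)
  for (i in 1:20) {
    xyz <- matrix(runif(18, 0, 7), 6, 3)
    at <- atoms_df(as.vector(t(xyz)), radius = runif(6, 1.4, 1.9),
                   group = rep(c("receptor", "conjugate"), each = 3))
    expect_gte(interface_area(at, n_sphere_points = 120), -1e-9)
  }
  expect_error(interface_area(atoms_df(c(0, 0, 0))), "separable|partner")
})

test_that("ddg is the rigid-separation energy difference", {
  # infinitely separated partners: zero
  far <- atoms_df(c(0, 0, 0, 50, 0, 0), radius = 1.7,
                  group = c("receptor", "conjugate"))
  expect_equal(ddg(far), 0)
  # single attractive contact at r0: -w_lj_atr * eps
  near <- atoms_df(c(0, 0, 0, 3.4, 0, 0), radius = 1.7,
                   group = c("receptor", "conjugate"))
  expect_equal(ddg(near), -0.2, tolerance = 1e-12)
  # 5-atom toy complex equals the hand-summed difference
  xyz <- rbind(c(0, 0, 0), c(3.2, 0, 0), c(0, 3.4, 0),
               c(1.8, 1.8, 2.5), c(-2.5, 1.5, 1.0))
  grp <- c("receptor", "receptor", "receptor", "conjugate", "conjugate")
  q <- c(0.3, -0.2, 0.1, -0.4, 0.25)
  at <- atoms_df(as.vector(t(xyz)), radius = 1.6, charge = q, group = grp)
  W <- energy_weights()
  pair_e <- function(i, j) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2)); r0 <- 3.2
    if (r > 10) return(0)
    v <- 0.2 * ((r0 / r)^12 - 2 * (r0 / r)^6)
    atr <- if (r >= r0) v else -0.2
    rep_ <- if (r < r0) v + 0.2 else 0
    W$w_lj_atr * atr + W$w_lj_rep * rep_ + W$w_elec * q[i] * q[j] / (4 * r^2)
  }
  hand <- 0
  for (i in 1:3) for (j in 4:5) hand <- hand + pair_e(i, j)
  expect_equal(ddg(at, W), hand, tolerance = 1e-9)
})

test_that("shape complementarity reaches its analytic limits on dot plates", {
  # parallel plates in registration, opposing normals, d -> 0: sc -> 1
  g <- as.matrix(expand.grid(x = seq(0, 5, by = 0.4), y = seq(0, 5, by = 0.4)))
  dots_a <- cbind(g, 0); dots_b <- cbind(g, 1e-4)
  n_a <- matrix(rep(c(0, 0, 1), nrow(g)), ncol = 3, byrow = TRUE)
  n_b <- -n_a
  r <- sc_from_dots(dots_a, n_a, dots_b, n_b)
  expect_gt(r$sc, 0.95)
  expect_lte(r$sc, 1 + 1e-9)
  # orthogonal plates: sc ~ 0
  dots_c <- cbind(g[, 1], 0.5, g[, 2])
  n_c <- matrix(rep(c(0, 1, 0), nrow(g)), ncol = 3, byrow = TRUE)
  r2 <- sc_from_dots(dots_a, n_a, dots_c, n_c)
  expect_lt(abs(r2$sc), 0.1)
  # bounded in [-1, 1] on random clouds that share a zone
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(runif(60, 0, 3), 20, 3)
    B <- A + matrix(rnorm(60, 0, 0.4), 20, 3)
    nA <- matrix(rnorm(60), 20, 3); nA <- nA / sqrt(rowSums(nA^2))
    nB <- matrix(rnorm(60), 20, 3); nB <- nB / sqrt(rowSums(nB^2))
    sc <- sc_from_dots(A, nA, B, nB)$sc
    expect_gte(sc, -1); expect_lte(sc, 1)
  }
  # distant partners raise the undefined-interface error
  expect_error(sc_from_dots(dots_a, n_a, dots_a + 100, n_a), "too far")
  m <- small_conjugate()
  sc_m <- shape_complementarity(m)
  expect_gte(sc_m, -1); expect_lte(sc_m, 1)
})

test_that("contact molecular surface is monotone and saturates on enclosure", {
  far <- atoms_df(c(0, 0, 0, 50, 0, 0), radius = 1.7,
                  group = c("receptor", "conjugate"))
  expect_equal(contact_molecular_surface(far), 0)
  m <- small_conjugate()
  c1 <- contact_molecular_surface(m, contact_distance = 1.0)
  c2 <- contact_molecular_surface(m, contact_distance = 1.5)
  c3 <- contact_molecular_surface(m, contact_distance = 2.5)
  expect_lte(c1, c2 + 1e-9); expect_lte(c2, c3 + 1e-9)
  # ligand atom wrapped tightly by a shell: contact area approaches the
  # ligand's total surface area (tolerance 10%)
  shell_pts <- 4.1 * lariatforge:::.fibonacci_sphere(200)
  at <- rbind(atoms_df(c(0, 0, 0), radius = 1.7, group = "conjugate"),
              atoms_df(as.vector(t(shell_pts)), radius = 1.7,
                       group = "receptor"))
  at$res_idx <- seq_len(nrow(at))
  cms <- contact_molecular_surface(at)
  expect_lt(abs(cms - 4 * pi * 1.7^2) / (4 * pi * 1.7^2), 0.10)
})

test_that("buried_unsats counts buried polar atoms without partners", {
  # an exposed carbonyl O with no partner is not buried, hence not counted
  exposed <- atoms_df(c(0, 0, 0), element = "O", name = "O",
                      acceptor = TRUE, radius = 1.52)
  expect_equal(buried_unsats(exposed), 0L)
  # engineered buried O: a tight apolar cage, with an N-H donor inside at
  # 2.9 A / 165-ish geometry -> satisfied; remove the donor -> 1 unsat
  cage_pts <- 5.2 * lariatforge:::.fibonacci_sphere(180)
  cage <- atoms_df(as.vector(t(cage_pts)), radius = 1.9)
  cage$res_idx <- cage$res_idx + 100L
  o <- data.frame(group = "all", res_idx = 1L, name = "O", element = "O",
                  x = 0, y = 0, z = 0, charge = -0.5, donor = FALSE,
                  acceptor = TRUE, radius = 1.52)
  n <- data.frame(group = "all", res_idx = 2L,
                  name = c("N", "H"), element = c("N", "H"),
                  x = c(0, 0), y = c(2.9, 1.9), z = c(0, 0),
                  charge = c(0.35, 0), donor = c(TRUE, FALSE),
                  acceptor = FALSE, radius = c(1.55, 1.2))
  sat <- rbind(o, n, cage)
  expect_equal(buried_unsats(sat), 0L)
  unsat <- rbind(o, cage)
  expect_equal(buried_unsats(unsat), 1L)
})

test_that("pocket_volume recovers analytic cavity volumes and flags open
           pockets", {
  # radius-6 spherical cavity: (4/3) pi 6^3 = 904.8 A^3 within 10%
  rec6 <- make_toy_pocket(toy_pocket_spec(cavity_radius = 6))
  pv <- pocket_volume(rec6, c(0, 0, 0))
  expect_lt(abs(pv$volume - 904.8) / 904.8, 0.10)
  expect_false(pv$open)
  # volume scales as the cube of the radius (finer grid for the small cavity)
  rec3 <- make_toy_pocket(toy_pocket_spec(cavity_radius = 3))
  pv3 <- pocket_volume(rec3, c(0, 0, 0), grid = 0.25)
  pv6 <- pocket_volume(rec6, c(0, 0, 0), grid = 0.25)
  expect_lt(abs(pv3$volume / pv6$volume - 1 / 8), 0.1 / 8)
  # a seed in bulk solvent floods to the box shell: open-pocket warning
  expect_warning(pocket_volume(rec6, c(30, 0, 0)), "open")
  # a seed inside an atom is an error
  shell_at <- rec6$atoms[1, ]
  expect_error(pocket_volume(rec6, as.numeric(shell_at[c("x", "y", "z")])),
               "inside an atom|not probe-accessible")
})

test_that("energy-based metrics are rigid-motion invariant", {
  m <- small_conjugate()
  at <- m$atoms
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  at2 <- at
  at2[, c("x", "y", "z")] <-
    sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(R), 2, c(3, -8, 12), "+")
  at2[, c("h_x", "h_y", "h_z")] <-
    sweep(as.matrix(at[, c("h_x", "h_y", "h_z")]) %*% t(R), 2, c(3, -8, 12), "+")
  at2[, c("ant_x", "ant_y", "ant_z")] <-
    sweep(as.matrix(at[, c("ant_x", "ant_y", "ant_z")]) %*% t(R), 2,
          c(3, -8, 12), "+")
  expect_equal(total_energy(at2), total_energy(at), tolerance = 1e-6)
  expect_equal(ddg(at2), ddg(at), tolerance = 1e-6)
  # quadrature-based areas are invariant to within the quadrature resolution
  a1 <- attr(sasa(at, n_sphere_points = 480), "total")
  a2 <- attr(sasa(at2, n_sphere_points = 480), "total")
  expect_lt(abs(a1 - a2) / a1, 0.01)
})
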