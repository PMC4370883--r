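test_that("flat-bottom restraints are zero inside bounds, quadratic outside", {
  m <- atomic_model(c("P", "P"), xyz = rbind(c(0, 0, 0), c(3, 0, 0)),
                    resno = c(1L, 2L))
  rs <- restraint_set(distances = data.frame(i = 1, j = 2, d_lo = 2, d_hi = 5,
                                             k = 1, class = "noe"),
                      repulsion_k = 0)
  expect_equal(restraint_energy(m, rs)$energy, 0)
  m6 <- set_coords(m, rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(restraint_energy(m6, rs)$energy, 1)      # (6 - 5)^2
  m1 <- set_coords(m, rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(restraint_energy(m1, rs)$energy, 1)      # (1 - 2)^2
})

test_that("bond and angle terms are harmonic with the stated minima", {
  m <- atomic_model(c("A", "B", "C"),
                    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 2, 0)))
  rs <- restraint_set(bonds = data.frame(i = 1, j = 2, d0 = 1.5, k = 100),
                      angles = data.frame(i = 1, j = 2, k_atom = 3,
                                          theta0 = 90, k = 10),
                      repulsion_k = 0)
  expect_equal(restraint_energy(m, rs)$energy, 0, tolerance = 1e-12)
  # stretching the bond along its own axis leaves the angle at 90 degrees
  m2 <- set_coords(m, rbind(c(-0.5, 0, 0), c(1.5, 0, 0), c(1.5, 2, 0)))
  e2 <- restraint_energy(m2, rs)
  expect_equal(as.numeric(e2$terms["bond"]), 100 * 0.25, tolerance = 1e-12)
  expect_equal(as.numeric(e2$terms["angle"]), 0, tolerance = 1e-12)
  th <- 60 * pi / 180
  m3 <- set_coords(m, rbind(c(cos(th) * 1.5, sin(th) * 1.5, 0),
                            c(0, 0, 0), c(1.5, 0, 0)))
  rs3 <- restraint_set(angles = data.frame(i = 1, j = 2, k_atom = 3,
                                           theta0 = 90, k = 10),
                       repulsion_k = 0)
  expect_equal(restraint_energy(m3, rs3)$energy, 10 * (pi / 6)^2,
               tolerance = 1e-10)
})

test_that("repulsion acts only on non-restrained pairs inside the radius", {
  m <- atomic_model(c("A", "B"), xyz = rbind(c(0, 0, 0), c(1, 0, 0)))
  rs <- restraint_set(repulsion_radius = 2.5, repulsion_k = 10)
  expect_equal(restraint_energy(m, rs)$energy, 10 * 1.5^2, tolerance = 1e-12)
  # bonded pairs are excluded
  rs2 <- restraint_set(bonds = data.frame(i = 1, j = 2, d0 = 1, k = 50),
                       repulsion_radius = 2.5, repulsion_k = 10)
  expect_equal(restraint_energy(m, rs2)$energy, 0, tolerance = 1e-12)
})

test_that("total restraint gradient matches finite differences", {
  set.seed(5)
  n <- 8
  m <- atomic_model(rep(c("P", "C", "N", "O"), 2),
                    xyz = matrix(rnorm(3 * n, sd = 2.5), n),
                    resno = rep(1:2, each = 4))
  rs <- restraint_set(
    distances = data.frame(i = c(1, 2, 3), j = c(5, 7, 8),
                           d_lo = c(2, 1, 3), d_hi = c(4, 2, 6),
                           k = c(30, 50, 5),
                           class = c("noe", "hbond", "pp")),
    bonds = data.frame(i = c(1, 4), j = c(2, 5), d0 = c(1.5, 2),
                       k = c(500, 500)),
    angles = data.frame(i = 1, j = 2, k_atom = 3, theta0 = 100, k = 20),
    repulsion_radius = 2.5, repulsion_k = 10)
  worst <- 0
  for (trial in 1:25) {
    X <- coords(m) + matrix(rnorm(3 * n, sd = 0.8), n)
    an <- restraint_energy(set_coords(m, X), rs)$gradient
    fd <- fd_gradient(function(Y) restraint_energy(set_coords(m, Y), rs)$energy,
                      X)
    scale <- pmax(abs(fd), 1e-8 * max(abs(fd), 1))
    worst <- max(worst, max(abs(an - fd) / scale))
  }
  expect_lt(worst, 1e-3)
})

test_that("energy is nonnegative and zero exactly at a satisfied geometry", {
  ref <- small_helix()
  rs <- toy_restraints(ref, seed = 2)
  e <- restraint_energy(ref, rs)
  expect_equal(e$energy, 0)
  set.seed(8)
  for (t in 1:5) {
    m <- perturb_model(ref, runif(1, 1, 6), seed = t)
    expect_gte(restraint_energy(m, rs)$energy, 0)
  }
})

test_that("restraints_from_pairs resolves names and rejects unknowns", {
  ref <- small_helix()
  rs <- restraints_from_pairs(ref, data.frame(
    res_i = 1, name_i = "P", res_j = 5, name_j = "P",
    d_lo = 16, d_hi = 20, class = "pp"))
  expect_equal(nrow(rs$distances), 1L)
  i <- rs$distances$i; j <- rs$distances$j
  expect_equal(ref$name[c(i, j)], c("P", "P"))
  expect_equal(ref$resno[c(i, j)], c(1L, 5L))
  expect_equal(rs$distances$k, 5)  # pp class default
  expect_error(restraints_from_pairs(ref, data.frame(
    res_i = 1, name_i = "XX", res_j = 2, name_j = "P",
    d_lo = 1, d_hi = 2, class = "noe")), "XX")
})

test_that("duplicate pairs within a class are dropped with a warning", {
  ref <- small_helix()
  tab <- data.frame(res_i = c(1, 1), name_i = "P", res_j = c(3, 3),
                    name_j = "P", d_lo = 5, d_hi = 12, class = "noe")
  expect_warning(rs <- restraints_from_pairs(ref, tab), "duplicate")
  expect_equal(nrow(rs$distances), 1L)
})

test_that("restraint tables round-trip through text", {
  ref <- small_helix()
  rs <- toy_restraints(ref, seed = 3)
  path <- withr::local_tempfile(fileext = ".tbl")
  write_restraint_table(ref, rs, path)
  rs2 <- read_restraint_table(path, ref)
  expect_equal(nrow(rs2$distances), nrow(rs$distances))
  expect_equal(sort(rs2$distances$i + 1000 * rs2$distances$j),
               sort(rs$distances$i + 1000 * rs$distances$j))
  expect_equal(restraint_energy(ref, rs2)$energy, 0, tolerance = 1e-8)
})

test_that("out-of-range restraint indices are rejected", {
  m <- tiny_model()
  rs <- restraint_set(distances = data.frame(i = 1, j = 9, d_lo = 1,
                                             d_hi = 2, k = 1, class = "noe"))
  expect_error(restraint_energy(m, rs), "out of range")
})
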