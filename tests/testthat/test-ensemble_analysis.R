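test_that("superposing a model onto itself is the identity", {
  m <- small_helix()
  fit <- kabsch_superpose(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a planted rotation and translation are recovered exactly", {
  m <- small_helix()
  R <- rot_z(37)
  tr <- c(5, -3, 12)
  target <- transform_model(m, R, tr)
  fit <- kabsch_superpose(m, target)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, tr, tolerance = 1e-8)
})

test_that("kabsch matches a brute-force rotational search on 4-atom sets", {
  # oracle: minimize RMSD over rotations parameterized by Euler angles,
  # polished from many random starts with optim
  brute_rmsd <- function(P, Q) {
    P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
    euler <- function(a) {
      ca <- cos(a); sa <- sin(a)
      Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
      Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
      Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
      Rz1 %*% Ry %*% Rz2
    }
    obj <- function(a) sqrt(mean(rowSums((P0 %*% t(euler(a)) - Q0)^2)))
    best <- Inf
    for (s in 1:40) {
      a0 <- runif(3, 0, 2 * pi)
      o <- optim(a0, obj, control = list(reltol = 1e-14, maxit = 2000))
      best <- min(best, o$value)
    }
    best
  }
  set.seed(17)
  for (case in 1:3) {
    P <- matrix(rnorm(12, sd = 3), 4)
    Q <- matrix(rnorm(12, sd = 3), 4)
    mp <- atomic_model(rep("C", 4), xyz = P)
    mq <- atomic_model(rep("C", 4), xyz = Q)
    expect_equal(kabsch_superpose(mp, mq)$rmsd, brute_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("reflections are excluded from the fitted rotation", {
  set.seed(23)
  P <- matrix(rnorm(15, sd = 3), 5)
  mirrored <- P %*% diag(c(-1, 1, 1))
  mp <- atomic_model(rep("C", 5), xyz = P)
  mq <- atomic_model(rep("C", 5), xyz = mirrored)
  fit <- kabsch_superpose(mp, mq)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)  # a proper rotation cannot undo a reflection
})

test_that("fitted RMSD agrees with an independent superposition library", {
  set.seed(41)
  a <- small_helix()
  for (t in 1:3) {
    b <- perturb_model(a, runif(1, 1, 6), seed = 40 + t)
    ours <- rmsd(a, b)
    theirs <- bio3d::rmsd(as.numeric(t(coords(a))), as.numeric(t(coords(b))),
                          fit = TRUE)
    # bio3d rounds its result to 3 decimals
    expect_equal(ours, theirs, tolerance = 1e-3)
  }
})

test_that("rmsd is symmetric and never exceeds the unsuperposed value", {
  set.seed(31)
  a <- small_helix()
  b <- perturb_model(a, 4, seed = 2)
  expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-10)
  raw <- sqrt(mean(rowSums((coords(a) - coords(b))^2)))
  expect_lte(rmsd(a, b), raw + 1e-12)
})

test_that("superposition errors on count mismatch and degenerate geometry", {
  a <- small_helix()
  b <- tiny_model()
  expect_error(kabsch_superpose(a, b), "differ")
  line <- atomic_model(rep("C", 4), xyz = cbind(1:4, 0, 0))
  fit <- kabsch_superpose(line, line)  # self-fit of collinear atoms is fine
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_error(kabsch_superpose(tiny_model()[1:2, ], tiny_model()[1:2, ]),
               "at least 3")
})

test_that("ensemble statistics match a direct 3-model computation", {
  base <- small_helix()
  m1 <- base
  m2 <- perturb_model(base, 2, seed = 1)
  m3 <- perturb_model(base, 3, seed = 2)
  st <- ensemble_stats(list(m1, m2, m3))
  direct <- c(rmsd(m1, m2), rmsd(m1, m3), rmsd(m2, m3))
  expect_equal(st$pairwise_rmsd_mean, mean(direct), tolerance = 1e-12)
  expect_equal(st$pairwise_rmsd_sd, sd(direct), tolerance = 1e-12)
  # accuracy against a reference
  st2 <- ensemble_stats(list(m2, m3), reference = m1)
  expect_equal(st2$reference_rmsd_mean, mean(c(rmsd(m2, m1), rmsd(m3, m1))),
               tolerance = 1e-12)
  # a single pair reports sd 0 by convention
  expect_equal(st2$pairwise_rmsd_sd, 0)
})

test_that("identical models give zero precision; rigid motion changes nothing", {
  base <- small_helix()
  st <- ensemble_stats(list(base, base, base))
  expect_equal(st$pairwise_rmsd_mean, 0, tolerance = 1e-12)
  expect_equal(st$pairwise_rmsd_sd, 0, tolerance = 1e-12)
  models <- list(base, perturb_model(base, 2, seed = 4),
                 perturb_model(base, 5, seed = 5))
  st0 <- ensemble_stats(models, reference = base)
  set.seed(6)
  R <- random_rotation()
  moved <- lapply(models, transform_model, rotation = R,
                  translation = c(30, -12, 4))
  st1 <- ensemble_stats(moved, reference = transform_model(base, R, c(30, -12, 4)))
  expect_equal(st1$pairwise_rmsd_mean, st0$pairwise_rmsd_mean, tolerance = 1e-8)
  expect_equal(st1$reference_rmsd_mean, st0$reference_rmsd_mean, tolerance = 1e-8)
})

test_that("hydrogens and pseudo atoms are outside the default heavy scope", {
  m <- small_helix()
  m$name[1] <- "H1"; m$is_hydrogen[1] <- TRUE
  m$is_pseudo[2] <- TRUE
  expect_equal(sum(heavy_atoms(m)), nrow(m) - 2L)
  # an ensemble whose members differ only in hydrogen positions is identical
  m2 <- m
  xyz <- coords(m2); xyz[1, ] <- xyz[1, ] + 5
  m2 <- set_coords(m2, xyz)
  st <- ensemble_stats(list(m, m2))
  expect_equal(st$pairwise_rmsd_mean, 0, tolerance = 1e-10)
})
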