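# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_helix <- function() cached("small_helix",
                                 build_toy_helix(toy_spec(n_residues = 10)))

small_map_10 <- function() cached("small_map_10", {
  simulate_map(small_helix(), simulation_params(10), default_selection)
})

# a tiny hand-specified 3-atom model
tiny_model <- function() {
  atomic_model(name = c("P", "C4'", "N1"),
               xyz = rbind(c(1, 2, 3), c(4, 5, 6), c(2, 1, 0)),
               resno = c(1L, 1L, 2L))
}

# independent Pearson evaluation, spelled out from the defining formula
# with population (1/N) statistics
pearson_by_hand <- function(a, b) {
  N <- length(a)
  am <- sum(a) / N; bm <- sum(b) / N
  sa <- sqrt(sum((a - am)^2) / N); sb <- sqrt(sum((b - bm)^2) / N)
  sum((a - am) * (b - bm)) / (N * sa * sb)
}

# central finite-difference gradient of f(X) (scalar), step h
fd_gradient <- function(f, X, h = 1e-4) {
  G <- X * 0
  for (a in seq_len(nrow(X))) for (d in 1:3) {
    Xp <- X; Xp[a, d] <- Xp[a, d] + h
    Xm <- X; Xm[a, d] <- Xm[a, d] - h
    G[a, d] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# rotation matrix about z by angle (degrees)
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
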