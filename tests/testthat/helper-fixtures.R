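# Shared fixture builders.

# two well-separated random template conformations for cluster tests
make_templates <- function(n_atoms = 10, sd = 3, seeds = c(1, 99)) {
  lapply(seeds, function(s) {
    set.seed(s)
    matrix(rnorm(3 * n_atoms, sd = sd), n_atoms, 3)
  })
}

# random rigid rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force minimum RMSD over a rotational grid (independent oracle for
# kabsch_rmsd on small atom sets): scans ZYZ Euler angles
grid_min_rmsd <- function(a, b, n = 24) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  angs <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  betas <- seq(0, pi, length.out = n %/% 2 + 1)
  rotz <- function(t) rbind(c(cos(t), -sin(t), 0),
                            c(sin(t), cos(t), 0), c(0, 0, 1))
  roty <- function(t) rbind(c(cos(t), 0, sin(t)),
                            c(0, 1, 0), c(-sin(t), 0, cos(t)))
  best <- Inf
  for (a1 in angs) for (b1 in betas) for (c1 in angs) {
    R <- rotz(a1) %*% roty(b1) %*% rotz(c1)
    v <- sqrt(mean(rowSums((ac - bc %*% R)^2)))
    if (v < best) best <- v
  }
  best
}
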