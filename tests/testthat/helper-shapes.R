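# Small fixture builders shared across the suite.

# A toy pairing over k = 2 * n_pairs + n_mid landmarks: pairs (2, k), (3, k-1),
# ... with midline indices 1 and (if k even) n_pairs + 2.
toy_pairing <- function(n_pairs, n_mid = 2L) {
  k <- 2L * n_pairs + n_mid
  pairing_scheme("toy", cbind(1L + seq_len(n_pairs), k + 1L - seq_len(n_pairs)),
                 midline = c(1L, if (n_mid > 1L) 1L + n_pairs + seq_len(n_mid - 1L)))
}

# Random left-right symmetric perturbation of a template: paired landmarks get
# mirrored displacements, midline landmarks move only along y.
rsym_perturbation <- function(template, pairing, sd = 0.01) {
  k <- nrow(template)
  d <- matrix(0, k, 2L)
  pr <- pairing$pairs
  d[pr[, 1L], ] <- matrix(rnorm(2L * nrow(pr), sd = sd), nrow(pr))
  d[pr[, 2L], 1L] <- -d[pr[, 1L], 1L]
  d[pr[, 2L], 2L] <- d[pr[, 1L], 2L]
  d[pairing$midline, 2L] <- rnorm(length(pairing$midline), sd = sd)
  template + d
}

# Random left-right antisymmetric displacement field (reflect-and-relabel of
# template + d equals template - d): paired landmarks share the x displacement
# and take opposite y displacements; midline landmarks move only along x.
ranti_field <- function(template, pairing, norm = 1e-4) {
  k <- nrow(template)
  d <- matrix(0, k, 2L)
  pr <- pairing$pairs
  d[pr[, 1L], ] <- matrix(rnorm(2L * nrow(pr)), nrow(pr))
  d[pr[, 2L], 1L] <- d[pr[, 1L], 1L]
  d[pr[, 2L], 2L] <- -d[pr[, 1L], 2L]
  d[pairing$midline, 1L] <- rnorm(length(pairing$midline))
  norm * d / sqrt(sum(d^2))
}

# Oracle projector onto the tangent space at a unit-size reference shape:
# removes translation, the scale direction, the rotation direction, and the
# normal component at the reference. Input and output are k x 2 matrices.
project_at <- function(d, ref) {
  d <- sweep(d, 2L, colMeans(d))
  rv <- as.vector(t(ref))
  rot <- as.vector(t(cbind(-ref[, 2L], ref[, 1L])))
  rot <- rot / sqrt(sum(rot^2))
  dv <- as.vector(t(d))
  dv <- dv - sum(dv * rv) * rv - sum(dv * rot) * rot
  matrix(dv, ncol = 2L, byrow = TRUE)
}

tangent_to_matrix <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

rotate_shape <- function(m, theta) {
  m %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
}

# Parameter sets for the simulator with every directional field switched off
# (fluctuating asymmetry and digitizing noise only).
null_params <- function(n_flowers, seed = NULL, ...) {
  simulation_params(n_flowers = n_flowers, compass_da = NULL,
                    relative_da = NULL, organ_da = NULL,
                    compass_size_effect = NULL, seed = seed, ...)
}
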