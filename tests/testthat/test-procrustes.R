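test_that("centroid size has the closed form, homogeneity and degeneracy", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), sqrt(8))
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(20), 10)
    c_ <- rnorm(1)
    expect_equal(centroid_size(m * c_), abs(c_) * centroid_size(m))
  }
  expect_equal(centroid_size(matrix(3.2, 5, 2)), 0)
  expect_error(centroid_size(matrix(1, 1, 2)), "at least 2")
})

test_that("GPA removes similarity transforms and is monotone", {
  set.seed(21)
  base <- matrix(rnorm(16), 8)
  rotated <- rotate_shape(base, pi / 2) * 2 + 5
  fit <- gpa(list(base, rotated))
  expect_lt(sqrt(sum((fit$tangent[1, ] - fit$tangent[2, ])^2)), 1e-10)

  shapes <- lapply(1:8, function(i) matrix(rnorm(16), 8))
  fit <- gpa(shapes)
  expect_true(all(diff(fit$objective) <= 1e-9))
  # zero mean tangent vector at convergence
  expect_lt(max(abs(colMeans(fit$tangent))), 1e-8)
  # aligned shapes: zero centroid, unit centroid size
  for (i in seq_along(shapes)) {
    m <- tangent_to_matrix(fit$aligned[i, ])
    expect_lt(max(abs(colMeans(m))), 1e-10)
    expect_equal(centroid_size(m), 1, tolerance = 1e-10)
  }
  expect_error(gpa(list(base)), "at least 2")
  expect_error(gpa(list(base, matrix(1, 8, 2))), "zero centroid size")
})

test_that("GPA consensus matches brute-force minimization of summed squared
           Procrustes distances", {
  set.seed(33)
  base <- matrix(rnorm(12), 6)
  shapes <- lapply(1:5, function(i) base + matrix(rnorm(12, sd = 0.3), 6))
  fit <- gpa(shapes, tol = 1e-12)

  # oracle: numerically minimize sum_i min_rot | e^{i theta} z_i - c |^2 over
  # an unconstrained consensus c (normalized inside the objective)
  zs <- lapply(shapes, function(m) {
    z <- complex(real = m[, 1], imaginary = m[, 2])
    z <- z - mean(z)
    z / sqrt(sum(Mod(z)^2))
  })
  obj <- function(par) {
    cc <- complex(real = par[1:6], imaginary = par[7:12])
    cc <- cc - mean(cc)
    cc <- cc / sqrt(sum(Mod(cc)^2))
    sum(vapply(zs, function(z) sum(Mod(z)^2) + 1 - 2 * Mod(sum(Conj(z) * cc)),
               0))
  }
  start <- as.vector(rbind(fit$consensus[, 1], fit$consensus[, 2]))
  start <- c(fit$consensus[, 1], fit$consensus[, 2]) + rnorm(12, sd = 0.05)
  opt <- optim(start, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  cc <- complex(real = opt$par[1:6], imaginary = opt$par[7:12])
  cc <- cc - mean(cc)
  cc <- cc / sqrt(sum(Mod(cc)^2))
  gc_ <- complex(real = fit$consensus[, 1], imaginary = fit$consensus[, 2])
  # full Procrustes distance between the two consensus estimates
  d2 <- 2 - 2 * Mod(sum(Conj(cc) * gc_))
  expect_lt(sqrt(max(d2, 0)), 1e-6)
  expect_equal(obj(start * 0 + c(Re(gc_), Im(gc_))), opt$value,
               tolerance = 1e-9)
})

test_that("reflect_relabel does the stated arithmetic and is an involution", {
  pr <- pairing_scheme("toy", cbind(1L, 2L), midline = 3L)
  x <- rbind(c(2, 1), c(-1, 1), c(0, 0))
  expect_equal(reflect_relabel(x, pr), rbind(c(1, 1), c(-2, 1), c(0, 0)))

  sym <- rbind(c(1, 1), c(-1, 1), c(0, 0))
  expect_equal(reflect_relabel(sym, pr), sym)

  set.seed(5)
  pr8 <- toy_pairing(3L)  # k = 8
  for (i in 1:5) {
    m <- matrix(rnorm(16), 8)
    expect_equal(reflect_relabel(reflect_relabel(m, pr8), pr8), m)
  }
  expect_error(reflect_relabel(matrix(0, 5, 2), pr8), "does not match")
})

test_that("object-symmetry decomposition: symmetric fixed point and exact
           additivity", {
  set.seed(61)
  tpl <- default_template("fall")
  pr <- default_pairing("fall")
  cfgs <- lapply(1:6, function(i) rsym_perturbation(tpl, pr, sd = 0.02))
  dec <- symmetry_decompose(cfgs, pr)
  expect_lt(max(sqrt(rowSums(dec$asymmetric^2))), 1e-10)
  expect_lt(max(abs(dec$symmetric + dec$asymmetric - dec$tangent)), 1e-12)
  # consensus is symmetric under reflect-and-relabel
  expect_lt(max(abs(reflect_relabel(dec$consensus, pr) - dec$consensus)), 1e-9)
})

test_that("reflecting the whole dataset flips asymmetric components only", {
  set.seed(62)
  tpl <- default_template("standard")
  pr <- default_pairing("standard")
  cfgs <- lapply(1:8, function(i) tpl + matrix(rnorm(38, sd = 0.01), 19))
  dec1 <- symmetry_decompose(cfgs, pr)
  dec2 <- symmetry_decompose(lapply(cfgs, reflect_relabel, pairing = pr), pr)
  expect_equal(dec2$symmetric, dec1$symmetric, tolerance = 1e-8)
  expect_equal(dec2$asymmetric, -dec1$asymmetric, tolerance = 1e-8)
})

test_that("an injected antisymmetric field is recovered in the asymmetric
           component", {
  set.seed(63)
  tpl <- default_template("fall")
  pr <- default_pairing("fall")
  fields <- lapply(1:3, function(i) ranti_field(tpl, pr, norm = 3e-4))
  cfgs <- lapply(rep(1:3, each = 2), function(i) tpl + fields[[i]])
  dec <- symmetry_decompose(cfgs, pr)
  for (j in seq_along(cfgs)) {
    expected <- project_at(fields[[rep(1:3, each = 2)[j]]], dec$consensus)
    expect_lt(max(abs(tangent_to_matrix(dec$asymmetric[j, ]) - expected)),
              1e-6)
  }
})

test_that("symmetric and asymmetric ranks partition the shape-space rank", {
  set.seed(64)
  tpl <- default_template("fall")
  pr <- default_pairing("fall")
  cfgs <- lapply(1:100, function(i) tpl + matrix(rnorm(36, sd = 0.01), 18))
  dec <- symmetry_decompose(cfgs, pr)
  nrank <- function(m) {
    ev <- eigen(cov(m), symmetric = TRUE, only.values = TRUE)$values
    sum(ev > 1e-8 * max(ev))
  }
  k <- 18
  expect_equal(nrank(dec$tangent), 2 * k - 4)
  expect_equal(nrank(dec$symmetric) + nrank(dec$asymmetric), 2 * k - 4)
  expect_equal(nrank(dec$symmetric), 16)
  expect_equal(nrank(dec$asymmetric), 16)
})
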