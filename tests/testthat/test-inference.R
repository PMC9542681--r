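test_that("one-way size ANOVA matches hand-computed sums of squares", {
  # two groups: {1, 2, 3}, {4, 6, 8}; hand computation:
  # means 2 and 6, grand 4; SSB = 3*(2-4)^2 + 3*(6-4)^2 = 24, df 1
  # SSW = (1 + 0 + 1) + (4 + 0 + 4) = 10, df 4; F = 24 / (10/4) = 9.6
  res <- anova_centroid_size(c(1, 2, 3, 4, 6, 8), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 9.6)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  expect_equal(res$p_value, pf(9.6, 1, 4, lower.tail = FALSE))
  expect_equal(res$table$mean, c(2, 6))
  expect_equal(res$table$se, c(1, 2) / sqrt(3))

  expect_equal(anova_centroid_size(c(1, 2, 3, 1, 2, 3),
                                   rep(c("a", "b"), each = 3))$F, 0)
  expect_warning(
    res <- anova_centroid_size(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3)),
    "infinite")
  expect_identical(res$F, Inf)
  expect_error(anova_centroid_size(1:4, c("a", "a", "a", "b")),
               "at least 2 groups")
})

test_that("Goodall's F: closed form, null case, scale invariance", {
  # group A = {(0,0),(1,0)}, group B = {(3,1),(4,1)}:
  # means (0.5,0), (3.5,1); SSB = 2*2.5 + 2*2.5 = 10, SSW = 4*0.25 = 1
  # F = (10/1) / (1/2) = 20
  x <- rbind(c(0, 0), c(1, 0), c(3, 1), c(4, 1))
  g <- rep(c("a", "b"), each = 2)
  expect_equal(goodall_f(x, g), 20)
  expect_equal(goodall_f(x * 7.3, g), 20)   # scale invariance of the ratio

  # equal group means by construction (each group centered) -> F = 0
  set.seed(71)
  a <- scale(matrix(rnorm(12), 4), scale = FALSE)
  b <- scale(matrix(rnorm(9), 3), scale = FALSE)
  expect_equal(goodall_f(rbind(a, b), rep(c("a", "b"), c(4, 3))), 0)

  expect_warning(f <- goodall_f(rbind(a * 0, b[1:3, ] * 0 + 5),
                                rep(c("a", "b"), c(4, 3))), "infinite")
  expect_identical(f, Inf)
})

test_that("Pillai's trace matches the eigenvalue oracle and its bounds", {
  set.seed(72)
  # full-rank small instance: brute-force eigen of solve(E) %*% H
  x <- matrix(rnorm(60), 15, 4)
  g <- factor(rep(1:3, each = 5))
  xc <- scale(x, scale = FALSE)
  m <- rowsum(xc, g) / 5
  h <- crossprod(m * sqrt(5))
  e <- crossprod(xc) - h
  lam <- eigen(solve(e) %*% h, only.values = TRUE)$values
  expect_equal(pillai_trace(x, g), sum(Re(lam) / (1 + Re(lam))),
               tolerance = 1e-10)

  # two fully separated 1-D groups with zero within-group variance:
  # rank reduction leaves one dimension where E = 0 -> Pillai = 1
  x1 <- matrix(c(0, 0, 1, 1), 4, 1)
  expect_equal(pillai_trace(x1, c("a", "a", "b", "b")), 1)

  # bound property: 0 <= Pillai <= min(G - 1, rank)
  for (i in 1:10) {
    n <- sample(8:20, 1); d <- sample(2:5, 1); G <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n)
    g <- factor(sample(G, n, replace = TRUE))
    if (min(table(g)) < 2 || nlevels(droplevels(g)) < 2) next
    v <- pillai_trace(x, g)
    expect_gte(v, -1e-12)
    expect_lte(v, min(nlevels(droplevels(g)) - 1, d) + 1e-12)
  }
  expect_error(pillai_trace(matrix(1, 6, 3), rep(c("a", "b"), 3)),
               "identical")
})

test_that("Goodall's F and Pillai's trace are rotation invariant", {
  set.seed(73)
  x <- matrix(rnorm(80), 20, 4)
  g <- factor(rep(1:4, 5))
  rot <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(goodall_f(x %*% rot, g), goodall_f(x, g))
  expect_equal(pillai_trace(x %*% rot, g), pillai_trace(x, g),
               tolerance = 1e-10)
})

test_that("permutation test: p-value conventions, determinism, enumeration", {
  set.seed(74)
  # observed statistic largest among sampled permutations -> p = 1/(n+1)
  x <- rbind(matrix(rnorm(24, sd = 0.05), 12),
             matrix(rnorm(24, sd = 0.05) + 40, 12))
  g <- rep(c("a", "b"), each = 12)
  r <- permutation_test(x, g, statistic = "goodall_f",
                        n_permutations = 199, seed = 42)
  expect_equal(r$results$p_value, 1 / 200)

  # identical data across groups, fixed seed -> exactly reproducible
  x0 <- matrix(rnorm(120), 30, 4)
  g0 <- factor(rep(1:3, 10))
  r1 <- permutation_test(x0, g0, n_permutations = 299, seed = 7)
  r2 <- permutation_test(x0, g0, n_permutations = 299, seed = 7)
  expect_identical(r1$results, r2$results)
  expect_true(all(r1$results$p_value >= 1 / 300 &
                  r1$results$p_value <= 1))

  # few distinct arrangements -> exhaustive enumeration with a note
  xs <- matrix(c(0, 1, 10, 11), 4, 1)
  gs <- rep(c("a", "b"), each = 2)
  expect_message(
    re <- permutation_test(xs, gs, statistic = "goodall_f",
                           n_permutations = 999),
    "exhaustively")
  expect_true(re$exhaustive)
  expect_equal(re$n_permutations, choose(4, 2))   # 6 arrangements
  # observed split and its mirror are the only two reaching the maximum
  expect_equal(re$results$p_value, 2 / 6)

  expect_error(permutation_test(x0, g0, n_permutations = 50), "at least 99")
})

test_that("flower-level permutation moves label blocks together", {
  set.seed(75)
  blocks <- split(1:12, rep(1:4, each = 3))
  for (i in 1:20) {
    idx <- floralsym:::permute_blocks(blocks)
    expect_equal(sort(idx), 1:12)
    # each destination block is filled from a single source block
    src <- (idx[seq(1, 12, by = 3)] - 1) %/% 3
    expect_equal(sort(unique((idx - 1) %/% 3)), 0:3)
    expect_true(all((idx - 1) %/% 3 == rep(src, each = 3)))
  }
  x <- matrix(rnorm(48), 12, 4)
  g <- factor(rep(rep(1:2, each = 3), 2))
  fid <- rep(1:4, each = 3)
  r1 <- permutation_test(x, g, n_permutations = 199, seed = 1,
                         unit = "flower", flower_ids = fid)
  r2 <- permutation_test(x, g, n_permutations = 199, seed = 1,
                         unit = "flower", flower_ids = fid)
  expect_identical(r1$results, r2$results)
  expect_error(permutation_test(x, g, n_permutations = 199, unit = "flower"),
               "flower_ids")
})

test_that("CVA: geometry, whitening, and the generalized-eigen oracle", {
  set.seed(76)
  # two spherical groups separated along the first coordinate axis
  x <- rbind(matrix(rnorm(200, sd = 0.2), 50, 4),
             cbind(rnorm(50, 10, 0.2), matrix(rnorm(150, sd = 0.2), 50, 3)))
  g <- rep(c("a", "b"), each = 50)
  res <- cva(x, g)
  expect_gt(abs(res$axes[1, 1]) / sqrt(sum(res$axes[, 1]^2)), 0.97)
  expect_equal(ncol(res$scores), 1L)          # G - 1 = 1 axis

  # pooled within-group covariance of the scores is the identity
  x3 <- matrix(rnorm(300), 50, 6)
  g3 <- factor(rep(1:5, 10))
  r3 <- cva(x3, g3)
  xc <- scale(r3$scores, scale = FALSE)
  m <- rowsum(xc, g3) / 10
  w <- (crossprod(xc) - crossprod(m * sqrt(10))) / (50 - 5)
  expect_equal(w, diag(ncol(r3$scores)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # brute-force oracle on a 10-observation, 6-variable, 3-group instance
  x10 <- matrix(rnorm(60), 10, 6)
  g10 <- factor(rep(1:3, c(4, 3, 3)))
  r10 <- cva(x10, g10)
  xc <- scale(x10, scale = FALSE)
  ng <- c(4, 3, 3)
  m <- rowsum(xc, g10) / ng
  h <- crossprod(m * sqrt(ng)) / (10 - 3)
  w <- (crossprod(xc) - crossprod(m * sqrt(ng))) / (10 - 3)
  ev <- eigen(solve(w) %*% h)
  ord <- order(Re(ev$values), decreasing = TRUE)
  expect_equal(r10$eigenvalues, Re(ev$values)[ord][1:2], tolerance = 1e-8)
  for (j in 1:2) {                       # axes parallel to oracle vectors
    a <- r10$axes[, j]; b <- Re(ev$vectors[, ord[j]])
    expect_equal(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-8)
  }

  # scores invariant (up to sign) to non-degenerate linear reparameterization
  amat <- matrix(rnorm(36), 6)
  r10b <- cva(x10 %*% amat, g10)
  for (j in 1:2) {
    cj <- cor(r10$scores[, j], r10b$scores[, j])
    expect_equal(abs(cj), 1, tolerance = 1e-6)
  }

  expect_error(cva(x10, rep("a", 10)), "at least 2 groups")
  expect_error(cva(x10[1:3, ], factor(c(1, 2, 3))), "more observations")
})

test_that("group mean shapes: identity, invariance, empty-group rejection", {
  set.seed(77)
  x <- matrix(rnorm(18), 3, 6)
  g <- factor(c("a", "b", "c"))
  gm <- group_mean_shapes(x, g)
  expect_equal(unname(gm$means), unname(x))
  expect_equal(gm$grand_mean, colMeans(x))
  expect_equal(unname(gm$differences), unname(sweep(x, 2, colMeans(x))))

  x2 <- matrix(rnorm(60), 10, 6)
  g2 <- factor(rep(1:2, 5))
  ord <- sample(10)
  gm1 <- group_mean_shapes(x2, g2)
  gm2 <- group_mean_shapes(x2[ord, ], g2[ord])
  expect_equal(gm1$means, gm2$means)

  expect_error(group_mean_shapes(x2, factor(g2, levels = c(1, 2, 3))),
               "empty group")
})

test_that("grouped shape samples validate their labeling invariants", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(grouped_shape_sample(x, rep("a", 10)), "at least 2 groups")
  expect_error(grouped_shape_sample(x, c(rep("a", 9), NA)), "non-missing")
  s <- grouped_shape_sample(x, rep(c("a", "b"), 5), "asymmetric",
                            flower_ids = rep(1:5, each = 2))
  expect_s3_class(s, "grouped_shape_sample")
  expect_equal(goodall_f(s), goodall_f(x, rep(c("a", "b"), 5)))
})
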