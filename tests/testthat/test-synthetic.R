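test_that("templates are exactly symmetric, unit sized, correctly paired", {
  for (ot in c("fall", "standard", "style_branch")) {
    tpl <- default_template(ot)
    pr <- default_pairing(ot)
    expect_equal(nrow(tpl), ORGAN_LANDMARKS[[ot]])
    expect_equal(centroid_size(tpl), 1, tolerance = 1e-12)
    expect_equal(reflect_relabel(tpl, pr), tpl)
    expect_equal(sort(c(as.vector(pr$pairs), pr$midline)),
                 seq_len(ORGAN_LANDMARKS[[ot]]))
  }
})

test_that("displacement fields have the stated symmetry and amplitude", {
  tpl <- default_template("fall")
  pr <- default_pairing("fall")
  bend <- bend_field(tpl, amplitude = 0.02)
  expect_equal(sqrt(sum(bend^2)), 0.02)
  # antisymmetric: reflect-relabel of template + d is template - d
  expect_equal(reflect_relabel(tpl + bend, pr), tpl - bend, tolerance = 1e-12)
  widen <- widen_field(tpl, amplitude = 0.015)
  expect_equal(sqrt(sum(widen^2)), 0.015)
  # symmetric: displaced template is still a fixed point
  expect_equal(reflect_relabel(tpl + widen, pr), tpl + widen,
               tolerance = 1e-12)
  cf <- compass_field(tpl, pr, amplitude_asym = 0.01, amplitude_sym = 0.005)
  expect_equal(dim(cf), c(6L, 18L, 2L))
  expect_equal(apply(cf, 2:3, mean), matrix(0, 18, 2))  # sectors sum to zero
  expect_equal(sqrt(mean(apply(cf, 1, function(m) sum(m^2)))),
               sqrt(0.01^2 + 0.005^2), tolerance = 1e-10)
})

test_that("generated datasets have the right structure and bookkeeping", {
  ds <- generate_dataset(simulation_params(n_flowers = 10, seed = 2))
  types <- vapply(ds$configs, `[[`, "", "organ_type")
  expect_equal(unname(table(types)[c("fall", "standard", "style_branch")]),
               rep(30L, 3), ignore_attr = TRUE)
  expect_equal(nrow(ds$records), 10L)
  organs <- join_metadata(ds$configs, ds$records)
  # whorl geometry: falls/styles at 0/120/240 relative for expected flowers,
  # standards always offset by 60
  for (f in ds$records$flower_id) {
    o <- organs[organs$flower_id == f, ]
    fr <- sort(o$relative_orientation[o$organ_type == "fall"])
    sr <- sort(o$relative_orientation[o$organ_type == "standard"])
    yr <- sort(o$relative_orientation[o$organ_type == "style_branch"])
    exp_f <- if (ds$records$alignment[ds$records$flower_id == f] == "expected")
      c(0, 120, 240) else c(60, 180, 300)
    expect_equal(fr, exp_f)
    expect_equal(yr, exp_f)
    expect_equal(sr, sort((exp_f + 60) %% 360))
  }
})

test_that("identical parameters and seed reproduce the dataset bit for bit", {
  p <- simulation_params(n_flowers = 6, seed = 123)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$records, d2$records)
  for (i in seq_along(d1$configs))
    expect_identical(d1$configs[[i]]$coords, d2$configs[[i]]$coords)
  d3 <- generate_dataset(simulation_params(n_flowers = 6, seed = 124))
  expect_false(identical(d1$configs[[1]]$coords, d3$configs[[1]]$coords))
})

test_that("with all randomness off, organs of a type are identical in shape", {
  p <- null_params(4, seed = 5, fa_sd = 0, noise_sd = 0)
  ds <- generate_dataset(p)
  falls <- organ_configs(ds, "fall")
  fit <- gpa(falls)
  d <- as.matrix(dist(fit$tangent))
  expect_lt(max(d), 1e-9)   # Procrustes distance 0 between any two falls
})

test_that("alignment mixture follows the expected-alignment probability", {
  p <- simulation_params(n_flowers = 462, p_expected_alignment = 0.68,
                         seed = 31)
  ds <- generate_dataset(p)
  frac <- mean(ds$records$alignment == "expected")
  ci <- 0.68 + c(-1, 1) * 1.96 * sqrt(0.68 * 0.32 / 462)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("parameter invariants are enforced", {
  expect_error(simulation_params(n_flowers = 0), "at least 1")
  bad_tpl <- lapply(setNames(nm = c("fall", "standard", "style_branch")),
                    default_template)
  bad_tpl$fall[2, 1] <- bad_tpl$fall[2, 1] + 0.1
  expect_error(simulation_params(templates = bad_tpl), "not symmetric")
  expect_error(simulation_params(fa_sd = -1), "fa_sd")
  expect_error(simulation_params(p_expected_alignment = 1.2),
               "p_expected_alignment")
  expect_error(simulation_params(spathe_orientation_weights = rep(0.2, 6)),
               "summing to 1")
})

test_that("simulator parameters round-trip through the YAML config", {
  p <- simulation_params(n_flowers = 3, seed = 77)
  path <- tempfile(fileext = ".yaml")
  write_simulation_params(p, path)
  p2 <- read_simulation_params(path)
  expect_equal(p2$templates, p$templates, tolerance = 1e-12)
  expect_equal(p2$compass_da, p$compass_da, tolerance = 1e-12)
  expect_equal(p2$organ_da, p$organ_da, tolerance = 1e-12)
  expect_null(p2$relative_da)
  expect_equal(p2$spathe_orientation_weights, p$spathe_orientation_weights)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p2)
  expect_equal(d1$configs[[5]]$coords, d2$configs[[5]]$coords,
               tolerance = 1e-9)
})
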