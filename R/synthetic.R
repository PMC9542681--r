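#' Parameters of the synthetic flower simulator
#'
#' Defines the generative model for synthetic *Iris*-like flowers: each
#' flower carries three falls, three standards and three style branches at
#' 60-degree-discretized orientations, and each organ's shape is the sum of
#' a symmetric template and several displacement fields with known,
#' controllable amplitudes — the layered "direction-giving factors" the
#' analysis is meant to disentangle:
#' \itemize{
#'   \item `compass_da`: per-compass-sector displacement (a consistent
#'     environmental gradient such as solar irradiance),
#'   \item `relative_da`: per-relative-sector displacement (anatomical
#'     position within the flower; zero by default, the study's observed
#'     condition),
#'   \item `organ_da`: a left-right antisymmetric field shared by all organs
#'     of a type (the "pinwheel" component),
#'   \item `fa_sd`: isotropic per-organ random shape deviation (fluctuating
#'     asymmetry),
#'   \item `noise_sd`: per-landmark digitizing error (mm).
#' }
#' Displacement fields and `fa_sd` are expressed in the organ's
#' unit-centroid-size frame and applied before size scaling; `noise_sd` is
#' applied in mm after scaling. Default sample structure follows the study
#' conditions: 462 flowers, expected-alignment probability 315/462, uniform
#' spathe sector weights, mean centroid sizes 350/354/217 mm with SDs
#' 43/44/24 mm, and alternating compass-linked size offsets of about 1-2%.
#'
#' @param n_flowers Number of flowers (>= 1).
#' @param templates Named list of unit-size symmetric template matrices for
#'   `fall`, `standard`, `style_branch`; must be exactly symmetric under
#'   [reflect_relabel()] with the matching pairing.
#' @param pairings Named list of [pairing_scheme()]s matching the templates.
#' @param mean_size,size_sd Named numeric vectors (mm) of the centroid-size
#'   distribution per organ type.
#' @param compass_size_effect Named list of length-6 per-sector additive
#'   size offsets (mm).
#' @param compass_da,relative_da Named lists of 6 x k x 2 sector
#'   displacement arrays, or `NULL` for no effect.
#' @param organ_da Named list of k x 2 antisymmetric displacement matrices,
#'   or `NULL`.
#' @param fa_sd,noise_sd Standard deviations (shape units / mm), >= 0.
#' @param p_expected_alignment Probability that a flower has a fall directly
#'   above the outer spathe (vs. rotated 60 degrees).
#' @param spathe_orientation_weights Probabilities over the six 60-degree
#'   spathe sectors (sum to 1).
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   dataset exactly.
#' @return Object of class `simulation_params`.
#' @seealso [generate_dataset()], [compass_field()], [bend_field()]
#' @export
simulation_params <- function(
    n_flowers = 462L,
    templates = lapply(setNames(nm = organ_types()), default_template),
    pairings = lapply(setNames(nm = organ_types()), default_pairing),
    mean_size = c(fall = 350, standard = 354, style_branch = 217),
    size_sd = c(fall = 43, standard = 44, style_branch = 24),
    compass_size_effect = list(fall = rep(c(-4, 4), 3),
                               standard = rep(c(4.5, -4.5), 3),
                               style_branch = rep(c(-2.5, 2.5), 3)),
    compass_da = lapply(templates, compass_field),
    relative_da = NULL,
    organ_da = lapply(templates, bend_field, amplitude = 0.01),
    fa_sd = 0.01, noise_sd = 0.05,
    p_expected_alignment = 315 / 462,
    spathe_orientation_weights = rep(1 / 6, 6),
    seed = NULL) {
  p <- structure(
    list(n_flowers = as.integer(n_flowers), templates = templates,
         pairings = pairings, mean_size = mean_size, size_sd = size_sd,
         compass_size_effect = compass_size_effect,
         compass_da = compass_da, relative_da = relative_da,
         organ_da = organ_da, fa_sd = fa_sd, noise_sd = noise_sd,
         p_expected_alignment = p_expected_alignment,
         spathe_orientation_weights = spathe_orientation_weights,
         seed = seed),
    class = "simulation_params")
  validate_simulation_params(p)
}

validate_simulation_params <- function(p) {
  if (is.na(p$n_flowers) || p$n_flowers < 1L)
    stop("`n_flowers` must be at least 1", call. = FALSE)
  for (ot in organ_types()) {
    tpl <- p$templates[[ot]]
    if (is.null(tpl)) stop("missing template for ", ot, call. = FALSE)
    if (nrow(tpl) != ORGAN_LANDMARKS[[ot]])
      stop(sprintf("template for %s must have %d landmarks", ot,
                   ORGAN_LANDMARKS[[ot]]), call. = FALSE)
    dev <- max(abs(reflect_relabel(tpl, p$pairings[[ot]]) - tpl))
    if (dev > 1e-8 * max(abs(tpl)))
      stop(sprintf(
        "template for %s is not symmetric under reflect-and-relabel (max deviation %.3g)",
        ot, dev), call. = FALSE)
  }
  stopifnot_number(p$fa_sd, "fa_sd", 0)
  stopifnot_number(p$noise_sd, "noise_sd", 0)
  stopifnot_number(p$p_expected_alignment, "p_expected_alignment", 0, 1)
  w <- p$spathe_orientation_weights
  if (length(w) != 6L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("`spathe_orientation_weights` must be 6 non-negative weights summing to 1",
         call. = FALSE)
  if (any(p$size_sd < 0) || any(p$mean_size <= 0))
    stop("sizes must be positive, size SDs non-negative", call. = FALSE)
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  amp <- function(fld) if (is.null(fld)) 0
    else signif(sqrt(mean(vapply(fld, function(a) sum(a^2) /
      (if (length(dim(a)) == 3L) dim(a)[1L] else 1L), 0))), 3)
  cat(sprintf(
    "<simulation_params> %d flowers | compass DA %s, relative DA %s, pinwheel DA %s\n",
    x$n_flowers, amp(x$compass_da), amp(x$relative_da), amp(x$organ_da)))
  cat(sprintf("  fa_sd %.3g (shape units), noise_sd %.3g mm, P(expected alignment) %.3g\n",
              x$fa_sd, x$noise_sd, x$p_expected_alignment))
  invisible(x)
}

whorl_offsets <- function(organ_type, alignment) {
  base <- if (alignment == "expected") c(0L, 120L, 240L) else c(60L, 180L, 300L)
  if (organ_type == "standard") (base + 60L) %% 360L else base
}

#' Generate a synthetic flower dataset
#'
#' Draws `n_flowers` flowers, each with three falls, three standards and
#' three style branches. The flower's outer-spathe orientation is drawn from
#' `spathe_orientation_weights`; with probability `p_expected_alignment` the
#' falls sit at relative orientations 0/120/240 (a fall directly above the
#' outer spathe) and otherwise the whole perianth is rotated by 60 degrees;
#' standards are offset 60 degrees from the falls. Each organ's shape is
#' template + compass field (by compass sector) + relative field (by
#' relative sector) + pinwheel field + fluctuating-asymmetry draw, scaled to
#' a drawn centroid size, placed at a random position and orientation on the
#' "scanner bed", and perturbed by mm-scale digitizing noise.
#'
#' @param params A [simulation_params()] object.
#' @return Object of class `flower_dataset`: `records` (data frame with
#'   `flower_id`, `plant_id`, `spathe_orientation`, `alignment`), `configs`
#'   (list of [landmark_config()]s, 9 per flower), and `params`.
#' @examples
#' ds <- generate_dataset(simulation_params(n_flowers = 5, seed = 1))
#' table(vapply(ds$configs, `[[`, "", "organ_type"))
#' @export
generate_dataset <- function(params) {
  validate_simulation_params(params)
  n <- params$n_flowers
  sectors <- seq(0L, 300L, by = 60L)
  with_seed(params$seed, {
    flower_id <- sprintf("F%04d", seq_len(n))
    plant_id <- sprintf("P%04d",
                        rep(seq_len(n), times = rep(c(2L, 1L), length.out = n))[seq_len(n)])
    spathe <- sample(sectors, n, replace = TRUE,
                     prob = params$spathe_orientation_weights)
    alignment <- ifelse(runif(n) < params$p_expected_alignment,
                        "expected", "rotated60")
    records <- data.frame(flower_id = flower_id, plant_id = plant_id,
                          spathe_orientation = spathe, alignment = alignment,
                          stringsAsFactors = FALSE)
    configs <- vector("list", 9L * n)
    ci <- 0L
    for (i in seq_len(n)) {
      for (ot in organ_types()) {
        tpl <- params$templates[[ot]]
        k <- nrow(tpl)
        offs <- whorl_offsets(ot, alignment[i])
        for (j in 1:3) {
          compass <- (spathe[i] + offs[j]) %% 360L
          rel <- (compass - spathe[i]) %% 360L
          shape <- tpl
          if (!is.null(params$compass_da))
            shape <- shape + params$compass_da[[ot]][compass %/% 60L + 1L, , ]
          if (!is.null(params$relative_da))
            shape <- shape + params$relative_da[[ot]][rel %/% 60L + 1L, , ]
          if (!is.null(params$organ_da))
            shape <- shape + params$organ_da[[ot]]
          if (params$fa_sd > 0)
            shape <- shape + matrix(rnorm(2L * k, sd = params$fa_sd), k)
          mu <- params$mean_size[[ot]] +
            (params$compass_size_effect[[ot]] %||% numeric(6))[compass %/% 60L + 1L]
          size <- max(rnorm(1L, mu, params$size_sd[[ot]]),
                      0.2 * params$mean_size[[ot]])
          coords <- shape / centroid_size(shape) * size
          theta <- runif(1L, 0, 2 * pi)
          rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
          coords <- coords %*% rot +
            matrix(runif(2L, -50, 50), k, 2L, byrow = TRUE)
          if (params$noise_sd > 0)
            coords <- coords + matrix(rnorm(2L * k, sd = params$noise_sd), k)
          ci <- ci + 1L
          configs[[ci]] <- landmark_config(
            coords, ot, organ_id = sprintf("%s_%s_%d", flower_id[i], ot, j),
            flower_id = flower_id[i], compass_orientation = compass)
        }
      }
    }
    structure(list(records = records, configs = configs, params = params),
              class = "flower_dataset")
  })
}

#' @export
print.flower_dataset <- function(x, ...) {
  cat(sprintf("<flower_dataset> %d flowers, %d organ configurations\n",
              nrow(x$records), length(x$configs)))
  print(table(alignment = x$records$alignment))
  invisible(x)
}

#' Subset a dataset's configurations by organ type
#'
#' @param dataset A `flower_dataset` (or plain list of configs).
#' @param organ_type Organ type to keep.
#' @return List of [landmark_config()]s.
#' @export
organ_configs <- function(dataset, organ_type) {
  organ_type <- match.arg(organ_type, organ_types())
  configs <- if (!is.null(dataset$configs)) dataset$configs else dataset
  configs[vapply(configs, `[[`, "", "organ_type") == organ_type]
}

## ---- YAML configuration ---------------------------------------------------

#' Read or write simulator parameters as a YAML config file
#'
#' Serializes every [simulation_params()] field; templates, pairings and
#' displacement fields are stored as nested numeric lists. Reading restores
#' the full parameter object (and validates it).
#'
#' @param path YAML file path.
#' @param params A [simulation_params()] object.
#' @return `read_simulation_params()` returns a [simulation_params()];
#'   `write_simulation_params()` returns `path` invisibly.
#' @export
read_simulation_params <- function(path) {
  y <- yaml::read_yaml(path)
  lst_mat <- function(l) if (is.null(l)) NULL else
    lapply(l, function(m) do.call(rbind, m))
  lst_arr <- function(l) if (is.null(l)) NULL else lapply(l, function(a) {
    mats <- lapply(a, function(m) do.call(rbind, m))
    out <- array(0, dim = c(length(mats), dim(mats[[1L]])))
    for (s in seq_along(mats)) out[s, , ] <- mats[[s]]
    out
  })
  simulation_params(
    n_flowers = y$n_flowers,
    templates = lst_mat(y$templates),
    pairings = lapply(y$pairings, function(pp)
      pairing_scheme(pp$organ_type, do.call(rbind, pp$pairs), pp$midline)),
    mean_size = unlist(y$mean_size), size_sd = unlist(y$size_sd),
    compass_size_effect = y$compass_size_effect,
    compass_da = lst_arr(y$compass_da), relative_da = lst_arr(y$relative_da),
    organ_da = lst_mat(y$organ_da),
    fa_sd = y$fa_sd, noise_sd = y$noise_sd,
    p_expected_alignment = y$p_expected_alignment,
    spathe_orientation_weights = y$spathe_orientation_weights,
    seed = y$seed)
}

#' @rdname read_simulation_params
#' @export
write_simulation_params <- function(params, path) {
  mat_lst <- function(l) if (is.null(l)) NULL else
    lapply(l, function(m) apply(m, 1L, as.numeric, simplify = FALSE))
  arr_lst <- function(l) if (is.null(l)) NULL else lapply(l, function(a)
    lapply(seq_len(dim(a)[1L]), function(s)
      apply(a[s, , ], 1L, as.numeric, simplify = FALSE)))
  y <- list(
    n_flowers = params$n_flowers,
    templates = mat_lst(params$templates),
    pairings = lapply(params$pairings, function(pp)
      list(organ_type = pp$organ_type,
           pairs = apply(pp$pairs, 1L, as.integer, simplify = FALSE),
           midline = as.integer(pp$midline))),
    mean_size = as.list(params$mean_size), size_sd = as.list(params$size_sd),
    compass_size_effect = params$compass_size_effect,
    compass_da = arr_lst(params$compass_da),
    relative_da = arr_lst(params$relative_da),
    organ_da = mat_lst(params$organ_da),
    fa_sd = params$fa_sd, noise_sd = params$noise_sd,
    p_expected_alignment = params$p_expected_alignment,
    spathe_orientation_weights = as.numeric(params$spathe_orientation_weights),
    seed = params$seed)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
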