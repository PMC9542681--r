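## Built-in symmetric organ templates and the displacement fields used by
## the synthetic generator. Templates are simple petal-like polygon outlines
## with the landmark counts of the real organs (fall 18, standard 19, style
## branch 18), exactly bilaterally symmetric about the y axis, normalized to
## unit centroid size. Landmark order: base midline, up the left margin,
## apex midline, down the right margin, plus organ-specific extra midline
## points.

petal_outline <- function(n_side, length, width, sharp = 1) {
  t <- seq_len(n_side) / (n_side + 1)
  cbind(x = -width * sin(pi * t)^sharp, y = length * t)
}

#' Built-in symmetric organ templates
#'
#' Synthetic mean shapes for the three floral organ types: petal-like
#' polygons with the organ's landmark count, exactly symmetric under
#' [reflect_relabel()] with the matching [default_pairing()], and normalized
#' to unit centroid size. Multiply by a centroid size in mm to obtain a
#' mm-scale configuration.
#'
#' @param organ_type `"fall"`, `"standard"` or `"style_branch"`.
#' @return A k x 2 coordinate matrix of unit centroid size.
#' @seealso [default_pairing()], [simulation_params()]
#' @export
default_template <- function(organ_type) {
  organ_type <- match.arg(organ_type, organ_types())
  m <- switch(organ_type,
    fall = {
      left <- petal_outline(8L, length = 3, width = 1.0)
      rbind(c(0, 0), left, c(0, 3), left[8:1, ] * cbind(rep(-1, 8), rep(1, 8)))
    },
    standard = {
      left <- petal_outline(8L, length = 3, width = 1.15, sharp = 0.8)
      rbind(c(0, 0), left, c(0, 3), left[8:1, ] * cbind(rep(-1, 8), rep(1, 8)),
            c(0, 2.6))
    },
    style_branch = {
      left <- petal_outline(7L, length = 2.2, width = 0.45, sharp = 0.8)
      rbind(c(0, 0), left, c(0, 1.9), c(0, 2.2),
            left[7:1, ] * cbind(rep(-1, 7), rep(1, 7)), c(0, 1.0))
    })
  m[abs(m) < 1e-15] <- 0
  m <- sweep(m, 2L, colMeans(m))
  unname(m / centroid_size(m))
}

#' Built-in pairing schemes for the synthetic templates
#'
#' Left/right landmark pairs and midline indices matching
#' [default_template()]. For real data the pairing must be supplied by the
#' user (see [read_pairing()]), since it depends on the digitization
#' protocol.
#'
#' @inheritParams default_template
#' @return A [pairing_scheme()].
#' @export
default_pairing <- function(organ_type) {
  organ_type <- match.arg(organ_type, organ_types())
  switch(organ_type,
    fall = pairing_scheme("fall",
      cbind(2:9, 18:11), midline = c(1L, 10L)),
    standard = pairing_scheme("standard",
      cbind(2:9, 18:11), midline = c(1L, 10L, 19L)),
    style_branch = pairing_scheme("style_branch",
      cbind(2:8, 17:11), midline = c(1L, 9L, 10L, 18L)))
}

## Remove the similarity components (translation, isotropic scale, rotation)
## of a displacement field at the given unit-size template, so that field
## amplitudes are expressed purely in the tangent space the analyses see.
project_tangent_field <- function(d, template) {
  d <- sweep(d, 2L, colMeans(d))
  tv <- flatten_coords(template)
  rot <- flatten_coords(cbind(-template[, 2L], template[, 1L]))
  rot <- rot / sqrt(sum(rot^2))
  dv <- flatten_coords(d)
  dv <- dv - sum(dv * tv) * tv - sum(dv * rot) * rot
  unflatten_coords(dv)
}

#' Antisymmetric "pinwheel" bending field
#'
#' A left-right antisymmetric displacement field (a lateral bend whose
#' magnitude grows quadratically along the organ's axis). Applied with the
#' same sign to every organ of a type it produces the pinwheel pattern of
#' whole-flower rotational symmetry: under [reflect_relabel()] the displaced
#' template maps to template minus field. The field is orthogonalized
#' against translation, scale and rotation at the template and normalized so
#' its tangent-space norm equals `amplitude` (unit-centroid-size shape
#' units).
#'
#' @param template Unit-size k x 2 template matrix.
#' @param amplitude Tangent-space norm of the field.
#' @return A k x 2 displacement matrix.
#' @export
bend_field <- function(template, amplitude = 0.01) {
  y <- template[, 2L]
  q <- ((y - mean(y)) / sd(y))^2
  d <- cbind(q - mean(q), 0)
  d <- project_tangent_field(d, template)
  amplitude * d / sqrt(sum(d^2))
}

#' Symmetric widening field
#'
#' A left-right symmetric displacement field expanding the organ's width
#' relative to its length (anisotropic widening, orthogonalized against
#' isotropic scale). Under [reflect_relabel()] the displaced template is
#' invariant, so the field lives entirely in the symmetric shape component.
#'
#' @inheritParams bend_field
#' @return A k x 2 displacement matrix of tangent norm `amplitude`.
#' @export
widen_field <- function(template, amplitude = 0.01) {
  d <- cbind(template[, 1L], 0)
  d <- project_tangent_field(d, template)
  amplitude * d / sqrt(sum(d^2))
}

#' Sector-keyed compass displacement field
#'
#' Builds a 6 x k x 2 array of displacement fields, one per 60-degree
#' orientation sector, emulating a smooth environmental gradient (e.g. solar
#' irradiance): an antisymmetric bend with magnitude proportional to
#' cos(sector angle) plus a smaller symmetric widening proportional to
#' sin(sector angle). Multipliers are scaled so the root-mean-square
#' tangent-space norm of the per-sector mean displacement equals
#' `amplitude_asym` (resp. `amplitude_sym`), and they sum to zero over the
#' six sectors.
#'
#' @inheritParams bend_field
#' @param pairing Pairing scheme for the template (used only for
#'   documentation symmetry checks; may be `NULL`).
#' @param amplitude_asym,amplitude_sym RMS per-sector amplitudes of the
#'   antisymmetric and symmetric parts, in unit-centroid-size shape units.
#' @return A 6 x k x 2 numeric array (sector, landmark, coordinate).
#' @export
compass_field <- function(template, pairing = NULL,
                          amplitude_asym = 0.008, amplitude_sym = 0.004) {
  k <- nrow(template)
  theta <- 2 * pi * (0:5) / 6
  asy <- bend_field(template, 1)
  sym <- widen_field(template, 1)
  out <- array(0, dim = c(6L, k, 2L))
  for (s in 1:6) {
    out[s, , ] <- sqrt(2) * cos(theta[s]) * amplitude_asym * asy +
      sqrt(2) * sin(theta[s]) * amplitude_sym * sym
  }
  out
}

zero_field <- function(k) array(0, dim = c(6L, k, 2L))
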