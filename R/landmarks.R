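#' Landmark counts per organ type
#'
#' Falls and style branches carry 18 landmarks, standards 19.
#'
#' @format Named integer vector with elements `fall`, `standard`,
#'   `style_branch`.
#' @export
ORGAN_LANDMARKS <- c(fall = 18L, standard = 19L, style_branch = 18L)

organ_types <- function() names(ORGAN_LANDMARKS)

#' Create a landmark configuration
#'
#' A landmark configuration is one floral organ's ordered set of 2D landmark
#' coordinates (in mm) together with its identity and orientation metadata.
#' Landmark indexing is 1-based throughout the package.
#'
#' @param coords Numeric k x 2 matrix of landmark coordinates (mm), one row
#'   per landmark, columns x and y.
#' @param organ_type One of `"fall"`, `"standard"`, `"style_branch"`. The
#'   landmark count k must match the type (18, 19, 18).
#' @param organ_id,flower_id Character identifiers.
#' @param compass_orientation Compass orientation of the organ in degrees
#'   clockwise from south, a multiple of 60 in `{0, 60, ..., 300}`, or `NA`.
#' @return An object of class `landmark_config`.
#' @examples
#' cfg <- landmark_config(default_template("fall"), "fall",
#'                        organ_id = "F1_fall_1", flower_id = "F1",
#'                        compass_orientation = 120)
#' centroid_size(cfg)
#' @export
landmark_config <- function(coords, organ_type,
                            organ_id = NA_character_,
                            flower_id = NA_character_,
                            compass_orientation = NA_integer_) {
  organ_type <- match.arg(organ_type, organ_types())
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("`coords` must be a k x 2 matrix", call. = FALSE)
  k <- nrow(coords)
  if (k != ORGAN_LANDMARKS[[organ_type]])
    stop(sprintf("organ '%s' (%s): expected %d landmarks, found %d",
                 organ_id, organ_type, ORGAN_LANDMARKS[[organ_type]], k),
         call. = FALSE)
  if (!all(is.finite(coords)))
    stop(sprintf("organ '%s': non-finite coordinates", organ_id), call. = FALSE)
  if (!is.na(compass_orientation)) check_sector(compass_orientation)
  structure(
    list(coords = unname(coords), organ_type = organ_type,
         organ_id = as.character(organ_id), flower_id = as.character(flower_id),
         compass_orientation = compass_orientation),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s (%s), flower %s, %d landmarks, compass %s\n",
              x$organ_id, x$organ_type, x$flower_id, nrow(x$coords),
              ifelse(is.na(x$compass_orientation), "?",
                     paste0(x$compass_orientation, "°"))))
  invisible(x)
}

config_coords <- function(x) {
  if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
}

check_sector <- function(deg) {
  bad <- !(deg %in% seq(0L, 300L, by = 60L))
  if (any(bad))
    stop("orientations must be multiples of 60 in {0, ..., 300}; offending value(s): ",
         paste(unique(deg[bad]), collapse = ", "), call. = FALSE)
  invisible(as.integer(deg))
}

#' Define a bilateral pairing scheme
#'
#' A pairing scheme declares which landmark indices form left/right pairs and
#' which lie on the organ's midline; together they must partition
#' `1:k`. The scheme defines the organ's internal bilateral symmetry used by
#' [reflect_relabel()] and [symmetry_decompose()].
#'
#' @param organ_type Organ type the scheme belongs to.
#' @param pairs Integer m x 2 matrix; column 1 holds left-side indices,
#'   column 2 the matching right-side indices.
#' @param midline Integer vector of unpaired (midline) landmark indices.
#' @return An object of class `pairing_scheme`.
#' @examples
#' default_pairing("standard")
#' @export
pairing_scheme <- function(organ_type, pairs, midline) {
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
  midline <- as.integer(midline)
  idx <- c(as.vector(pairs), midline)
  k <- length(idx)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(k)))
    stop(sprintf("pairs and midline must partition 1..%d for organ type '%s'",
                 k, organ_type), call. = FALSE)
  if (organ_type %in% organ_types() && k != ORGAN_LANDMARKS[[organ_type]])
    stop(sprintf("pairing for '%s' must cover %d landmarks, found %d",
                 organ_type, ORGAN_LANDMARKS[[organ_type]], k), call. = FALSE)
  structure(list(organ_type = organ_type, pairs = pairs, midline = midline),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat(sprintf("<pairing_scheme> %s: %d pairs, midline {%s}\n", x$organ_type,
              nrow(x$pairs), paste(x$midline, collapse = ", ")))
  invisible(x)
}

## Permutation q with q[l] = r, q[r] = l, q[m] = m.
pairing_permutation <- function(pairing, k) {
  q <- seq_len(k)
  q[pairing$pairs[, 1L]] <- pairing$pairs[, 2L]
  q[pairing$pairs[, 2L]] <- pairing$pairs[, 1L]
  q
}
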