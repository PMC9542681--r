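#' Orientation of an organ relative to the outer spathe
#'
#' Subtracts the spathe's compass orientation from the organ's compass
#' orientation, adding 360 degrees when the result is negative — i.e. the
#' clockwise angle from the outer spathe to the organ. Both angles are
#' recorded to the nearest 60 degrees, 0 = south, clockwise positive.
#'
#' @param organ_compass,spathe_compass Degrees, multiples of 60 in
#'   `{0, ..., 300}`. Vectorized.
#' @return Integer degrees in `{0, 60, ..., 300}`.
#' @examples
#' relative_orientation(0, 300)   # 60
#' relative_orientation(60, 180)  # 240
#' @export
relative_orientation <- function(organ_compass, spathe_compass) {
  check_sector(organ_compass)
  check_sector(spathe_compass)
  as.integer((organ_compass - spathe_compass) %% 360L)
}

#' Classify a flower's alignment with the outer spathe
#'
#' A flower follows the expected floral ground plan when one of its falls
#' sits directly above the outer spathe, i.e. the falls have relative
#' orientations `{0, 120, 240}`; when the falls are at `{60, 180, 300}` the
#' flower is rotated by 60 degrees from that arrangement.
#'
#' @param fall_relative Integer vector of the relative orientations of a
#'   flower's falls (at least one).
#' @return `"expected"` or `"rotated60"`.
#' @examples
#' classify_alignment(c(0, 120, 240))
#' @export
classify_alignment <- function(fall_relative) {
  if (length(fall_relative) < 1L || anyNA(fall_relative))
    stop("need at least one fall with known relative orientation", call. = FALSE)
  check_sector(fall_relative)
  if (all(fall_relative %in% c(0L, 120L, 240L))) return("expected")
  if (all(fall_relative %in% c(60L, 180L, 300L))) return("rotated60")
  stop("inconsistent relative orientations among falls: ",
       paste(fall_relative, collapse = ", "), call. = FALSE)
}

#' Chi-square test of spathe-orientation uniformity
#'
#' Pearson chi-square test of the six 60-degree sector counts against equal
#' expected counts (df = 5).
#'
#' @param counts Six non-negative sector counts (0, 60, ..., 300 degrees),
#'   total > 0.
#' @return List with `chi_square`, `df`, `p_value` and `expected`.
#' @examples
#' orientation_uniformity_test(c(77, 77, 77, 77, 77, 77))$chi_square  # 0
#' @export
orientation_uniformity_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 6L || any(counts < 0) || any(!is.finite(counts)))
    stop("`counts` must be six non-negative sector counts", call. = FALSE)
  if (sum(counts) <= 0)
    stop("total count must be positive", call. = FALSE)
  ht <- suppressWarnings(chisq.test(counts))
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = unname(ht$expected))
}

#' Orientation summary of a flower dataset
#'
#' Tabulates organ counts per compass sector and per relative sector, and
#' the split of flowers between the expected alignment and the
#' 60-degree-rotated alignment.
#'
#' @param organs Annotated organ table from [join_metadata()].
#' @param path Optional CSV path to write the summary to.
#' @return List with `compass` and `relative` count tables (organ type x
#'   sector) and `alignment` (flower counts per alignment class).
#' @export
orientation_summary <- function(organs, path = NULL) {
  sectors <- seq(0L, 300L, by = 60L)
  tab <- function(col) {
    t <- table(factor(organs$organ_type, organ_types()),
               factor(organs[[col]], sectors))
    as.data.frame.matrix(t)
  }
  falls <- organs[organs$organ_type == "fall", ]
  ali <- vapply(split(falls$relative_orientation, falls$flower_id),
                classify_alignment, "")
  out <- list(compass = tab("compass_orientation"),
              relative = tab("relative_orientation"),
              alignment = table(factor(ali, c("expected", "rotated60"))))
  if (!is.null(path)) {
    comp <- cbind(grouping = "compass", organ_type = rownames(out$compass),
                  out$compass)
    rel <- cbind(grouping = "relative", organ_type = rownames(out$relative),
                 out$relative)
    write.csv(rbind(comp, rel), path, row.names = FALSE)
  }
  out
}
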