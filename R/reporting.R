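## Visual outputs: thin-plate-spline shape-difference diagrams at a stated
## exaggeration, and canonical-variate score plots with group-mean
## confidence ellipses.

#' Thin-plate-spline warp of an outline between two shapes
#'
#' Fits the 2D thin-plate spline interpolant mapping the reference
#' landmarks onto `reference + exaggeration * (target - reference)` and maps
#' an outline polyline through it. Landmarks map exactly; an exaggeration of
#' 15 (the default) amplifies subtle mean-shape differences enough to be
#' visible.
#'
#' @param reference k x 2 reference landmarks (e.g. the consensus), not
#'   collinear, no duplicates.
#' @param target k x 2 target landmarks (e.g. a group mean), same count.
#' @param outline Optional m x 2 polyline in the reference frame (defaults
#'   to the reference landmarks as a polygon).
#' @param exaggeration Positive displacement multiplier (default 15).
#' @return Object of class `tps_warp`: `landmarks_warped`, `outline`,
#'   `outline_warped`, `bending_energy`, `exaggeration`, and `warp_fun`
#'   (maps any m x 2 point set through the spline).
#' @examples
#' ref <- default_template("fall")
#' w <- tps_warp(ref, ref)          # identity
#' max(abs(w$outline_warped - w$outline))
#' @export
tps_warp <- function(reference, target, outline = NULL, exaggeration = 15) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!all(dim(reference) == dim(target)) || ncol(reference) != 2L)
    stop("reference and target must be k x 2 matrices of equal size",
         call. = FALSE)
  stopifnot_number(exaggeration, "exaggeration", lower = .Machine$double.eps)
  k <- nrow(reference)
  if (anyDuplicated(round(reference, 12L)))
    stop("duplicate reference landmarks make the TPS kernel singular",
         call. = FALSE)
  if (qr(cbind(1, reference))$rank < 3L)
    stop("collinear reference landmarks make the TPS system singular",
         call. = FALSE)
  outline <- if (is.null(outline)) reference else as.matrix(outline)

  q <- reference + exaggeration * (target - reference)
  kk <- tps_kernel(reference, reference)
  p <- cbind(1, reference)
  l <- rbind(cbind(kk, p), cbind(t(p), matrix(0, 3L, 3L)))
  coefs <- solve(l, rbind(q, matrix(0, 3L, 2L)))
  w <- coefs[seq_len(k), , drop = FALSE]
  a <- coefs[k + 1:3, , drop = FALSE]
  warp_fun <- function(pts) {
    pts <- as.matrix(pts)
    tps_kernel(pts, reference) %*% w + cbind(1, pts) %*% a
  }
  structure(list(
    landmarks_warped = q, outline = outline,
    outline_warped = warp_fun(outline),
    bending_energy = sum(diag(t(w) %*% kk %*% w)),
    exaggeration = exaggeration, reference = reference, target = target,
    warp_fun = warp_fun), class = "tps_warp")
}

## U(r) = r^2 log r, evaluated as 0.5 * r^2 * log(r^2); U(0) = 0.
tps_kernel <- function(a, b) {
  r2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  r2[r2 < .Machine$double.eps] <- 1           # log(1) = 0 at coincidence
  0.5 * r2 * log(r2)
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> %d landmarks, exaggeration %g, bending energy %.4g\n",
              nrow(x$landmarks_warped), x$exaggeration, x$bending_energy))
  invisible(x)
}

#' Plot a thin-plate-spline shape-difference diagram
#'
#' Reference outline dashed, warped (exaggerated) outline solid, with the
#' warped landmark positions.
#'
#' @param x A [tps_warp()] object.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tps_warp <- function(x, main = sprintf("shape difference (x%g)",
                                            x$exaggeration), ...) {
  rng <- apply(rbind(x$outline, x$outline_warped), 2L, range)
  plot(NA, xlim = rng[, 1L], ylim = rng[, 2L], asp = 1,
       xlab = "", ylab = "", main = main, axes = FALSE, ...)
  polygon(x$outline, border = "grey60", lty = 2L)
  polygon(x$outline_warped, border = "black", lwd = 2L)
  points(x$landmarks_warped, pch = 16L, cex = 0.6)
  invisible(x)
}

#' Canonical-variate score plot with group-mean confidence ellipses
#'
#' Plots CV scores, group means and per-group confidence ellipses of the
#' means on two canonical axes, and returns the ellipse parameters
#' numerically. With a single retained axis a 1-D interval plot is drawn
#' instead (with a note).
#'
#' @param result A [cva()] result.
#' @param axes Two axis indices (default CV1, CV2).
#' @param draw Set `FALSE` to skip plotting and only return the table.
#' @param ... Passed to [graphics::plot()].
#' @return Ellipse-parameter data frame (group, n, center, semi-axes, angle
#'   in radians of the major axis), invisibly when `draw = TRUE`.
#' @export
cv_ellipse_plot <- function(result, axes = c(1L, 2L), draw = TRUE, ...) {
  stopifnot(inherits(result, "cva_result"))
  g <- result$groups
  if (ncol(result$scores) < 2L) {
    message("single retained canonical axis; drawing 1-D interval plot")
    sc <- result$scores[, 1L]
    m <- tapply(sc, g, mean)
    se <- tapply(sc, g, function(v) sd(v) / sqrt(length(v)))
    if (draw) {
      plot(seq_along(m), m, pch = 16L, xaxt = "n", xlab = "group",
           ylab = "CV1", ylim = range(c(m - 2 * se, m + 2 * se)), ...)
      graphics::axis(1L, seq_along(m), names(m))
      segments(seq_along(m), m - 2 * se, seq_along(m), m + 2 * se)
    }
    return(invisible(data.frame(group = names(m), center1 = as.vector(m),
                                se = as.vector(se))))
  }
  sc <- result$scores[, axes, drop = FALSE]
  ell <- mean_ellipses(sc, g, result$conf)
  if (draw) {
    cols <- hcl.colors(nlevels(g), "Dark 3")
    plot(sc, col = adjustcolor(cols[as.integer(g)], 0.35), pch = 16L,
         cex = 0.5, asp = 1,
         xlab = paste0("CV", axes[1L]), ylab = paste0("CV", axes[2L]), ...)
    for (i in seq_len(nrow(ell))) {
      if (is.na(ell$semi_major[i])) next
      tt <- seq(0, 2 * pi, length.out = 120L)
      rot <- ell$angle[i]
      ex <- ell$semi_major[i] * cos(tt); ey <- ell$semi_minor[i] * sin(tt)
      lines(ell$center1[i] + ex * cos(rot) - ey * sin(rot),
            ell$center2[i] + ex * sin(rot) + ey * cos(rot),
            col = cols[i], lwd = 2L)
      points(ell$center1[i], ell$center2[i], col = cols[i], pch = 3L)
    }
    legend("topright", legend = ell$group, col = cols, lwd = 2L, bty = "n",
           cex = 0.8)
  }
  invisible(ell)
}
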