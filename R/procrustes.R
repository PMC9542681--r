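#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. For
#' mm-scale coordinates the result is in mm.
#'
#' @param x A [landmark_config()] or a k x 2 coordinate matrix, k >= 2.
#' @return Non-negative scalar; zero only if all landmarks coincide.
#' @examples
#' centroid_size(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) # sqrt(8)
#' @export
centroid_size <- function(x) {
  m <- config_coords(x)
  if (nrow(m) < 2L)
    stop("centroid size requires at least 2 landmarks", call. = FALSE)
  sqrt(sum(sweep(m, 2L, colMeans(m))^2))
}

## --- complex-arithmetic helpers (2D shapes as complex k-vectors) ---------

as_complex_config <- function(m) complex(real = m[, 1L], imaginary = m[, 2L])

complex_to_real <- function(z) {
  ## length-2k real vector, landmark-major (x1, y1, x2, y2, ...)
  as.vector(rbind(Re(z), Im(z)))
}

## reflect about the y axis then relabel: z -> (-Conj(z))[q]
reflect_relabel_complex <- function(z, q) (-Conj(z))[q]

## optimal rotation of unit pre-shape z onto c (least squares)
align_phase <- function(w) {
  mod <- Mod(w)
  out <- w / mod
  out[mod == 0] <- 1 + 0i
  out
}

symmetrize_consensus <- function(cns, q) {
  rc <- reflect_relabel_complex(cns, q)
  w <- sum(Conj(rc) * cns)
  rc <- rc * align_phase(w)
  cs <- (cns + rc) / 2
  cs / sqrt(sum(Mod(cs)^2))
}

## rotate a reflection-symmetric consensus so reflect_relabel fixes it
## exactly (phase phi with R(c) = e^{i phi} c removed by e^{i phi/2}),
## then orient it "tip up" deterministically.
canonicalize_symmetric <- function(cns, q) {
  rc <- reflect_relabel_complex(cns, q)
  phi <- Arg(sum(Conj(cns) * rc))
  cns <- cns * exp(1i * phi / 2)
  far <- which.max(Mod(cns))
  if (Im(cns[far]) < 0 ||
      (Im(cns[far]) == 0 && Re(cns[far]) < 0)) cns <- -cns
  cns
}

#' Generalized Procrustes superimposition
#'
#' Translates each configuration to zero centroid, scales it to unit
#' centroid size (partial Procrustes), and iteratively rotates all
#' configurations to the current consensus, re-estimating the consensus as
#' the normalized mean until it changes by less than `tol`. Shape
#' coordinates are finally projected orthogonally onto the tangent space at
#' the consensus, giving one common linear space for all downstream
#' statistics.
#'
#' @param configs List of [landmark_config()]s or k x 2 matrices with a
#'   common landmark count k.
#' @param tol Convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter Maximum number of iterations (default 100).
#' @param symmetrize Optional [pairing_scheme()]; if given, the consensus is
#'   symmetrized under reflect-and-relabel at every iteration (used by
#'   [symmetry_decompose()]).
#' @return An object of class `gpa_fit` with elements
#'   \describe{
#'     \item{tangent}{n x 2k matrix of tangent-space shape coordinates
#'       (landmark-major x,y column order).}
#'     \item{aligned}{n x 2k matrix of aligned unit-size coordinates before
#'       tangent projection.}
#'     \item{consensus}{k x 2 consensus (mean shape), unit centroid size.}
#'     \item{centroid_sizes}{Original centroid sizes (mm).}
#'     \item{iterations, objective}{Iteration count and the per-iteration
#'       sum of squared deviations from the consensus (non-increasing).}
#'   }
#' @examples
#' shapes <- lapply(1:4, function(i) default_template("fall") + 0.01 * i)
#' fit <- gpa(shapes)
#' fit$iterations
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L, symmetrize = NULL) {
  if (length(configs) < 2L)
    stop("GPA requires at least 2 configurations", call. = FALSE)
  mats <- lapply(configs, config_coords)
  k <- unique(vapply(mats, nrow, 1L))
  if (length(k) != 1L)
    stop("all configurations must share the same landmark count", call. = FALSE)
  n <- length(mats)
  Z <- t(vapply(mats, as_complex_config, complex(k)))
  Z <- Z - rowMeans(Z)
  sizes <- sqrt(rowSums(Mod(Z)^2))
  if (any(sizes < .Machine$double.eps * k))
    stop("degenerate configuration(s) with zero centroid size at index ",
         paste(which(sizes < .Machine$double.eps * k), collapse = ", "),
         call. = FALSE)
  Z <- Z / sizes
  q <- if (!is.null(symmetrize)) pairing_permutation(symmetrize, k)

  cns <- Z[1L, ]
  if (!is.null(q)) cns <- symmetrize_consensus(cns, q)
  cns <- cns / sqrt(sum(Mod(cns)^2))
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    phase <- align_phase(as.vector(Conj(Z) %*% cns))
    Z <- Z * phase                     # column-major recycling rotates rows
    objective[iter] <- sum(Mod(sweep(Z, 2L, cns))^2)
    new_cns <- colMeans(Z)
    new_cns <- new_cns / sqrt(sum(Mod(new_cns)^2))
    if (!is.null(q)) new_cns <- symmetrize_consensus(new_cns, q)
    delta <- sqrt(sum(Mod(new_cns - cns)^2))
    cns <- new_cns
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf(
        "GPA did not converge in %d iterations (last consensus change %.3e, tol %.1e)",
        max_iter, delta, tol), call. = FALSE)
  }
  if (!is.null(q)) cns <- canonicalize_symmetric(cns, q)
  Z <- Z * align_phase(as.vector(Conj(Z) %*% cns))   # final rotation pass

  X <- t(apply(Z, 1L, complex_to_real))
  cvec <- complex_to_real(cns)
  Tg <- X - (X %*% cvec) %*% t(cvec)                 # tangent projection
  colnames(X) <- colnames(Tg) <- coord_names(k)
  ids <- vapply(seq_along(configs), function(i) {
    cc <- configs[[i]]
    if (inherits(cc, "landmark_config") && !is.na(cc$organ_id)) cc$organ_id
    else as.character(i)
  }, "")
  rownames(X) <- rownames(Tg) <- ids
  structure(
    list(tangent = Tg, aligned = X,
         consensus = unflatten_coords(cvec),
         centroid_sizes = sizes, iterations = iter, objective = objective),
    class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d configurations, %d landmarks, %d iterations\n",
              nrow(x$tangent), nrow(x$consensus), x$iterations))
  invisible(x)
}

#' Reflect and relabel a configuration
#'
#' Negates the x coordinates (reflection about the y axis) and then swaps
#' the labels of each left/right landmark pair; midline labels are
#' unchanged. Applying the operation twice restores the input. The choice of
#' reflection axis is immaterial after Procrustes superimposition.
#'
#' @param x A [landmark_config()] or k x 2 matrix.
#' @param pairing A [pairing_scheme()] partitioning `1:k`.
#' @return Same type as `x`, reflected and relabeled.
#' @examples
#' tpl <- default_template("fall")
#' all.equal(reflect_relabel(tpl, default_pairing("fall")), tpl)
#' @export
reflect_relabel <- function(x, pairing) {
  m <- config_coords(x)
  k <- nrow(m)
  if (2L * nrow(pairing$pairs) + length(pairing$midline) != k)
    stop("pairing scheme does not match landmark count", call. = FALSE)
  q <- pairing_permutation(pairing, k)
  refl <- cbind(-m[, 1L], m[, 2L])[q, , drop = FALSE]
  if (inherits(x, "landmark_config")) {
    x$coords <- unname(refl)
    x
  } else unname(refl)
}

#' Decompose shape variation under bilateral object symmetry
#'
#' Runs a joint generalized Procrustes fit of the original configurations
#' and a reflected-and-relabeled copy of each (with the consensus
#' constrained to be symmetric). Each organ's symmetric shape component is
#' the average of its aligned original and aligned reflected copy; its
#' asymmetric component is the aligned original minus the symmetric
#' component (half the original-vs-reflection difference), so the two
#' components add back to the aligned original exactly.
#'
#' @inheritParams gpa
#' @param pairing A [pairing_scheme()] for the organ type.
#' @return An object of class `symmetry_decomposition`:
#'   \describe{
#'     \item{symmetric, asymmetric}{n x 2k tangent-space component matrices.}
#'     \item{tangent}{n x 2k aligned original tangent coordinates
#'       (= symmetric + asymmetric).}
#'     \item{consensus}{Symmetric consensus shape (k x 2).}
#'     \item{centroid_sizes}{Original centroid sizes (mm).}
#'     \item{meta}{Data frame of organ metadata when inputs are
#'       [landmark_config()]s.}
#'   }
#' @examples
#' cfgs <- replicate(4, default_template("fall") +
#'                     matrix(rnorm(36, sd = 0.005), 18), simplify = FALSE)
#' dec <- symmetry_decompose(cfgs, default_pairing("fall"))
#' max(abs(dec$symmetric + dec$asymmetric - dec$tangent))
#' @export
symmetry_decompose <- function(configs, pairing, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L)
    stop("need at least 2 configurations", call. = FALSE)
  n <- length(configs)
  reflected <- lapply(configs, reflect_relabel, pairing = pairing)
  fit <- gpa(c(configs, reflected), tol = tol, max_iter = max_iter,
             symmetrize = pairing)
  orig <- fit$tangent[seq_len(n), , drop = FALSE]
  refl <- fit$tangent[n + seq_len(n), , drop = FALSE]
  sym <- (orig + refl) / 2
  asym <- orig - sym
  meta <- NULL
  if (all(vapply(configs, inherits, TRUE, "landmark_config"))) {
    meta <- data.frame(
      organ_id = vapply(configs, `[[`, "", "organ_id"),
      flower_id = vapply(configs, `[[`, "", "flower_id"),
      organ_type = vapply(configs, `[[`, "", "organ_type"),
      compass_orientation = vapply(configs, function(cc)
        as.integer(cc$compass_orientation %||% NA), 1L),
      stringsAsFactors = FALSE)
  }
  structure(
    list(symmetric = sym, asymmetric = asym, tangent = orig,
         consensus = fit$consensus,
         centroid_sizes = fit$centroid_sizes[seq_len(n)],
         iterations = fit$iterations, pairing = pairing, meta = meta),
    class = "symmetry_decomposition")
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat(sprintf(
    "<symmetry_decomposition> %d organs, %d landmarks (%d pairs + %d midline)\n",
    nrow(x$tangent), nrow(x$consensus), nrow(x$pairing$pairs),
    length(x$pairing$midline)))
  cat(sprintf("  mean asymmetric norm: %.4g\n",
              mean(sqrt(rowSums(x$asymmetric^2)))))
  invisible(x)
}

#' Export aligned shapes or components as a CSV matrix
#'
#' One row per organ; columns in landmark-major x,y order
#' (`x1, y1, x2, y2, ...`).
#'
#' @param x A `gpa_fit` or `symmetry_decomposition`.
#' @param path Output CSV path.
#' @param what For decompositions: `"tangent"`, `"symmetric"` or
#'   `"asymmetric"`.
#' @return `path`, invisibly.
#' @export
write_shape_matrix <- function(x, path, what = "tangent") {
  m <- if (inherits(x, "symmetry_decomposition"))
    x[[match.arg(what, c("tangent", "symmetric", "asymmetric"))]]
  else x$tangent
  write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
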