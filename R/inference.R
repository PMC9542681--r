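## Group-comparison statistics on tangent-space shape coordinates:
## Goodall's F, Pillai's trace, permutation tests, CVA, size ANOVA.

#' Bundle shape vectors with a grouping factor
#'
#' A grouped shape sample holds a matrix of tangent-space shape vectors
#' (one row per organ), the orientation group of each organ, which shape
#' component the vectors are (symmetric or asymmetric), and the flower ID of
#' each organ for exchangeability bookkeeping in flower-level permutation.
#'
#' @param x Numeric n x d matrix of tangent vectors.
#' @param groups Grouping factor (or vector) of length n, no missing values.
#' @param component `"symmetric"` or `"asymmetric"` (tag only).
#' @param flower_ids Optional length-n vector of flower IDs.
#' @return Object of class `grouped_shape_sample`.
#' @export
grouped_shape_sample <- function(x, groups, component = c("symmetric", "asymmetric"),
                                 flower_ids = NULL) {
  x <- as.matrix(x)
  groups <- droplevels(factor(groups))
  if (nrow(x) != length(groups) || anyNA(groups))
    stop("every row of `x` needs exactly one non-missing group label",
         call. = FALSE)
  if (nlevels(groups) < 2L || sum(table(groups) >= 2L) < 2L)
    stop("need at least 2 groups with at least 2 members each", call. = FALSE)
  structure(list(x = x, groups = groups, component = match.arg(component),
                 flower_ids = flower_ids),
            class = "grouped_shape_sample")
}

## Accept either a grouped_shape_sample or (x, groups).
resolve_sample <- function(x, groups) {
  if (inherits(x, "grouped_shape_sample"))
    list(x = x$x, groups = x$groups, flower_ids = x$flower_ids)
  else {
    groups <- droplevels(factor(groups))
    if (nrow(as.matrix(x)) != length(groups) || anyNA(groups))
      stop("`groups` must label every row of `x`", call. = FALSE)
    list(x = as.matrix(x), groups = groups, flower_ids = NULL)
  }
}

#' Extract a shape component matrix from a decomposition
#'
#' @param decomp A [symmetry_decompose()] result.
#' @param component `"symmetric"`, `"asymmetric"` or `"tangent"`.
#' @return n x 2k matrix.
#' @export
component_matrix <- function(decomp, component = c("symmetric", "asymmetric",
                                                   "tangent")) {
  stopifnot(inherits(decomp, "symmetry_decomposition"))
  decomp[[match.arg(component)]]
}

#' Goodall's F statistic
#'
#' Ratio of the between-group to the within-group mean squared Procrustes
#' distance in tangent space:
#' \deqn{F = \frac{\sum_g n_g \|\bar x_g - \bar x\|^2 / (G - 1)}
#'            {\sum_g \sum_i \|x_{gi} - \bar x_g\|^2 / (N - G)}.}
#'
#' @param x n x d matrix of tangent vectors, or a [grouped_shape_sample()].
#' @param groups Grouping factor (ignored if `x` is a sample object).
#' @return The F value; `Inf` (with a warning) when the within-group
#'   dispersion is zero.
#' @export
goodall_f <- function(x, groups = NULL) {
  s <- resolve_sample(x, groups)
  ss <- group_ss(scale(s$x, scale = FALSE), s$groups)
  G <- nlevels(s$groups); N <- length(s$groups)
  if (ss$within <= 0) {
    warning("zero within-group dispersion; Goodall's F is infinite")
    return(Inf)
  }
  (ss$between / (G - 1)) / (ss$within / (N - G))
}

## between/within sums of squares of a centered matrix
group_ss <- function(xc, groups) {
  ng <- as.vector(table(groups))
  m <- rowsum(xc, groups) / ng
  between <- sum(ng * rowSums(m^2))
  list(between = between, within = sum(xc^2) - between, ng = ng, means = m)
}

#' Pillai's trace
#'
#' MANOVA statistic \eqn{\mathrm{tr}\,[H (H + E)^{-1}]} with between-group
#' (H) and within-group (E) cross-product matrices. Because tangent-space
#' shape components are rank-deficient by construction, the data are first
#' projected onto the principal subspace of the total scatter H + E
#' (eigenvalues > `tol` times the largest); the statistic is computed on
#' that retained-rank subspace.
#'
#' @inheritParams goodall_f
#' @param tol Relative rank tolerance (default 1e-8).
#' @return Pillai's trace, within `[0, min(G - 1, rank)]`.
#' @export
pillai_trace <- function(x, groups = NULL, tol = 1e-8) {
  s <- resolve_sample(x, groups)
  xc <- scale(s$x, scale = FALSE)
  red <- reduce_total(xc, tol)
  pillai_reduced(red$xr, s$groups, red$tinv)
}

## Orthonormal basis of the span of the centered data (total-scatter
## eigenvectors above tol), plus the inverse of the reduced total SSCP.
reduce_total <- function(xc, tol = 1e-8) {
  tt <- crossprod(xc)
  et <- eigen(tt, symmetric = TRUE)
  keep <- et$values > tol * max(et$values, 0)
  if (!any(keep))
    stop("all observations identical: total scatter has rank 0", call. = FALSE)
  v <- et$vectors[, keep, drop = FALSE]
  xr <- xc %*% v
  list(xr = xr, basis = v, tinv = diag(1 / et$values[keep],
                                       nrow = sum(keep)))
}

pillai_reduced <- function(xr, groups, tinv) {
  ng <- as.vector(table(groups))
  m <- rowsum(xr, groups) / ng
  h <- crossprod(m * sqrt(ng))
  sum(tinv * h)           # = trace(tinv %*% h), both symmetric
}

#' Group mean shapes and their differences
#'
#' Per-group mean tangent vectors, the grand mean, and each group's
#' difference from the grand mean (for visualization, e.g. via
#' [tps_warp()]).
#'
#' @inheritParams goodall_f
#' @return List with `means` (G x d), `grand_mean`, `differences`
#'   (means minus grand mean) and `n` per group.
#' @export
group_mean_shapes <- function(x, groups = NULL) {
  if (is.factor(groups) && any(table(groups) == 0L))
    stop("empty group(s): ",
         paste(names(which(table(groups) == 0L)), collapse = ", "),
         call. = FALSE)
  s <- resolve_sample(x, groups)
  ng <- table(s$groups)
  m <- rowsum(s$x, s$groups) / as.vector(ng)
  grand <- colMeans(s$x)
  list(means = m, grand_mean = grand,
       differences = sweep(m, 2L, grand), n = as.vector(ng))
}

#' Permutation test of shape differences among orientation groups
#'
#' Tests the null hypothesis of no differences among groups by permuting
#' group labels, with Goodall's F and/or Pillai's trace as test statistics.
#' The p-value uses the add-one convention
#' \eqn{p = (\#\{F^* \ge F\} + 1) / (n_{perm} + 1)}. When the number of
#' distinct label arrangements is at most `n_permutations` (organ unit
#' only), all arrangements are enumerated instead and the p-value is exact.
#'
#' Labels can be permuted across organs (default) or across whole flowers
#' (each flower's set of labels moves as a block; organs within a flower may
#' be correlated, which flower-level permutation respects).
#'
#' @inheritParams goodall_f
#' @param statistic Character vector from `c("goodall_f", "pillai")`; both
#'   statistics share the same permutations.
#' @param n_permutations Number of permutation iterations (>= 99; default
#'   10000).
#' @param seed Integer seed for reproducibility.
#' @param unit Exchangeable unit: `"organ"` or `"flower"`.
#' @param flower_ids Flower IDs (required for `unit = "flower"` unless `x`
#'   is a [grouped_shape_sample()] carrying them).
#' @param tol Relative rank tolerance for Pillai's trace.
#' @return Object of class `permutation_test` with a `results` data frame
#'   (statistic, observed, p_value) plus `n_permutations`, `seed`, `unit`,
#'   `exhaustive`.
#' @export
permutation_test <- function(x, groups = NULL,
                             statistic = c("goodall_f", "pillai"),
                             n_permutations = 10000L, seed = NULL,
                             unit = c("organ", "flower"),
                             flower_ids = NULL, tol = 1e-8) {
  s <- resolve_sample(x, groups)
  statistic <- match.arg(statistic, c("goodall_f", "pillai"),
                         several.ok = TRUE)
  unit <- match.arg(unit)
  if (n_permutations < 99L)
    stop("`n_permutations` must be at least 99", call. = FALSE)
  g <- s$groups
  N <- length(g); G <- nlevels(g)
  xc <- scale(s$x, scale = FALSE)
  red <- reduce_total(xc, tol)
  xr <- red$xr
  tot_ss <- sum(xr^2)
  ng <- as.vector(table(g))

  stat_fun <- function(labels) {
    m <- rowsum(xr, labels) / ng
    between <- sum(ng * rowSums(m^2))
    out <- c()
    if ("goodall_f" %in% statistic) {
      within <- tot_ss - between
      out["goodall_f"] <- if (within <= 0) Inf
        else (between / (G - 1)) / (within / (N - G))
    }
    if ("pillai" %in% statistic) {
      h <- crossprod(m * sqrt(ng))
      out["pillai"] <- sum(red$tinv * h)
    }
    out
  }
  observed <- stat_fun(g)

  exhaustive <- FALSE
  if (unit == "organ") {
    log_arr <- lgamma(N + 1) - sum(lgamma(ng + 1))
    if (log_arr <= log(n_permutations)) {
      exhaustive <- TRUE
      perms <- multiset_permutations(as.integer(g))
      n_permutations <- nrow(perms)
      message(sprintf(
        "only %d distinct label arrangements; enumerating exhaustively",
        n_permutations))
      stats <- vapply(seq_len(nrow(perms)), function(i)
        stat_fun(factor(levels(g)[perms[i, ]], levels(g))), observed)
      if (length(statistic) == 1L)
        stats <- matrix(stats, nrow = 1L, dimnames = list(statistic))
      eps <- 1e-12 * pmax(1, abs(observed))
      p <- rowMeans(stats >= observed - eps)
    }
  }
  if (!exhaustive) {
    blocks <- NULL
    if (unit == "flower") {
      fid <- s$flower_ids %||% flower_ids
      if (is.null(fid))
        stop("flower-level permutation requires `flower_ids`", call. = FALSE)
      blocks <- split(seq_len(N), fid)
    }
    stats <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        gl <- if (is.null(blocks)) g[sample.int(N)]
              else g[permute_blocks(blocks)]
        stat_fun(gl)
      }, observed)
    })
    if (length(statistic) == 1L) stats <- matrix(stats, nrow = 1L,
                                                 dimnames = list(statistic))
    eps <- 1e-12 * pmax(1, abs(observed))
    p <- (rowSums(stats >= observed - eps) + 1) / (n_permutations + 1)
  }
  structure(list(
    results = data.frame(statistic = names(observed),
                         observed = unname(observed),
                         p_value = unname(p[names(observed)]),
                         row.names = NULL),
    n_permutations = n_permutations, seed = seed, unit = unit,
    exhaustive = exhaustive), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> %d %spermutations (unit: %s)\n",
              x$n_permutations, if (x$exhaustive) "exhaustive " else "",
              x$unit))
  print(x$results, row.names = FALSE)
  invisible(x)
}

## All distinct permutations of a multiset of integer codes (rows).
multiset_permutations <- function(codes) {
  lv <- sort(unique(codes))
  counts <- tabulate(match(codes, lv))
  n <- length(codes)
  out <- list()
  rec <- function(counts, prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in seq_along(lv)) {
      if (counts[j] > 0L) {
        counts[j] <- counts[j] - 1L
        rec(counts, c(prefix, j))
        counts[j] <- counts[j] + 1L
      }
    }
  }
  rec(counts, integer(0))
  do.call(rbind, out)
}

## Permute whole-flower label blocks among flowers with equal organ counts;
## returns an index vector into the original labels.
permute_blocks <- function(blocks) {
  sizes <- lengths(blocks)
  idx <- integer(sum(sizes))
  for (sz in unique(sizes)) {
    members <- which(sizes == sz)
    from <- members[sample.int(length(members))]
    idx[unlist(blocks[members], use.names = FALSE)] <-
      unlist(blocks[from], use.names = FALSE)
  }
  idx
}

#' Canonical variate analysis of orientation groups
#'
#' Maximizes between-group relative to within-group shape variation. The
#' data are first projected onto the principal subspace where the pooled
#' within-group covariance has eigenvalues above `tol` times its largest
#' (shape components are rank-deficient by construction), the generalized
#' eigenproblem is solved there, and scores are whitened so the pooled
#' within-group covariance of the scores is the identity.
#'
#' @inheritParams goodall_f
#' @param tol Relative rank tolerance for the within-group covariance.
#' @param conf Confidence level of the group-mean ellipses (default 0.95).
#' @return Object of class `cva_result`: `axes` (d x m), `scores` (n x m),
#'   `eigenvalues`, `group_means` (scores), `ellipses` (per-group
#'   mean-confidence ellipse parameters on CV1-CV2), `groups`, `rank`.
#' @export
cva <- function(x, groups = NULL, tol = 1e-8, conf = 0.95) {
  s <- resolve_sample(x, groups)
  g <- s$groups
  N <- length(g); G <- nlevels(g)
  if (G < 2L) stop("CVA needs at least 2 groups", call. = FALSE)
  if (N <= G) stop("CVA needs more observations than groups", call. = FALSE)
  xc <- scale(s$x, scale = FALSE)
  ng <- as.vector(table(g))
  m <- rowsum(xc, g) / ng
  w <- (crossprod(xc) - crossprod(m * sqrt(ng))) / (N - G)
  ew <- eigen(w, symmetric = TRUE)
  keep <- ew$values > tol * max(ew$values, 0)
  if (!any(keep))
    stop("within-group covariance has rank 0", call. = FALSE)
  r <- sum(keep)
  u <- ew$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ew$values[keep]), nrow = r)    # whitening basis
  mw <- m %*% u
  b <- crossprod(mw * sqrt(ng)) / (N - G)        # between-group, whitened
  eb <- eigen(b, symmetric = TRUE)
  mdim <- min(G - 1L, r)
  e <- eb$vectors[, seq_len(mdim), drop = FALSE]
  axes <- u %*% e
  ## deterministic sign: largest-|loading| element of each axis positive
  for (j in seq_len(mdim)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- xc %*% axes
  colnames(scores) <- paste0("CV", seq_len(mdim))
  gm <- rowsum(scores, g) / ng
  ell <- if (mdim >= 2L) mean_ellipses(scores[, 1:2, drop = FALSE], g, conf)
  structure(list(axes = axes, scores = scores,
                 eigenvalues = eb$values[seq_len(mdim)],
                 group_means = gm, ellipses = ell, groups = g,
                 rank = r, conf = conf), class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("<cva_result> %d groups, %d axes (within-rank %d)\n",
              nlevels(x$groups), ncol(x$scores), x$rank))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

## Per-group confidence ellipses for the mean on two score axes: sample
## score covariance scaled by 1/n_g, chi-square(2) quantile.
mean_ellipses <- function(scores2, groups, conf = 0.95) {
  q <- qchisq(conf, df = 2)
  lv <- levels(groups)
  out <- data.frame(group = lv, n = as.vector(table(groups)),
                    center1 = NA_real_, center2 = NA_real_,
                    semi_major = NA_real_, semi_minor = NA_real_,
                    angle = NA_real_)
  for (i in seq_along(lv)) {
    sc <- scores2[groups == lv[i], , drop = FALSE]
    out$center1[i] <- mean(sc[, 1L]); out$center2[i] <- mean(sc[, 2L])
    if (nrow(sc) >= 2L) {
      ec <- eigen(cov(sc) / nrow(sc), symmetric = TRUE)
      out$semi_major[i] <- sqrt(q * max(ec$values[1L], 0))
      out$semi_minor[i] <- sqrt(q * max(ec$values[2L], 0))
      out$angle[i] <- atan2(ec$vectors[2L, 1L], ec$vectors[1L, 1L])
    }
  }
  out
}

#' One-way ANOVA of centroid size by orientation group
#'
#' Classical one-way analysis of variance of centroid size (mm) with an
#' orientation grouping factor, reported with per-group means and standard
#' errors.
#'
#' @param sizes Numeric vector of centroid sizes (mm).
#' @param groups Grouping factor, at least 2 groups with 2 members each.
#' @return Object of class `size_anova`: `F`, `df_between`, `df_within`,
#'   `p_value`, and `table` (group, n, mean, se).
#' @export
anova_centroid_size <- function(sizes, groups) {
  groups <- droplevels(factor(groups))
  if (length(sizes) != length(groups) || anyNA(sizes) || anyNA(groups))
    stop("`sizes` and `groups` must be complete and of equal length",
         call. = FALSE)
  tabn <- table(groups)
  if (nlevels(groups) < 2L || sum(tabn >= 2L) < 2L)
    stop("need at least 2 groups with at least 2 members", call. = FALSE)
  fit <- lm(sizes ~ groups)
  an <- suppressWarnings(anova(fit))  # anova.lm warns separately on perfect fits
  fval <- an$`F value`[1L]; pval <- an$`Pr(>F)`[1L]
  if (an$`Sum Sq`[2L] <= 1e-12 * sum(an$`Sum Sq`) || !is.finite(fval)) {
    warning("zero within-group variance; F reported as infinite")
    fval <- Inf; pval <- 0
  }
  tab <- data.frame(
    group = levels(groups), n = as.vector(tabn),
    mean = as.vector(tapply(sizes, groups, mean)),
    se = as.vector(tapply(sizes, groups, function(v)
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)))
  structure(list(F = fval, df_between = an$Df[1L], df_within = an$Df[2L],
                 p_value = pval, table = tab), class = "size_anova")
}

#' @export
print.size_anova <- function(x, ...) {
  cat(sprintf("<size_anova> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
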