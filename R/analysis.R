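## End-to-end conveniences tying the modules together: decompose one organ
## type, group by compass or relative orientation, test and ordinate.

#' Decompose one organ type of a dataset
#'
#' Subsets the dataset to one organ type, runs the bilateral
#' object-symmetry decomposition, and attaches the orientation metadata.
#'
#' @param dataset A `flower_dataset` from [generate_dataset()] or the list
#'   returned by [read_dataset()].
#' @param organ_type Organ type to analyze.
#' @param pairing Pairing scheme; defaults to the dataset's own (synthetic)
#'   pairing or the built-in one.
#' @return A [symmetry_decompose()] result whose `meta` additionally holds
#'   `spathe_orientation`, `relative_orientation` and `alignment`.
#' @export
decompose_organ <- function(dataset, organ_type, pairing = NULL) {
  organ_type <- match.arg(organ_type, organ_types())
  pairing <- pairing %||% dataset$params$pairings[[organ_type]] %||%
    dataset$pairings[[organ_type]] %||% default_pairing(organ_type)
  cfgs <- organ_configs(dataset, organ_type)
  dec <- symmetry_decompose(cfgs, pairing)
  rec <- dataset$records
  i <- match(dec$meta$flower_id, rec$flower_id)
  dec$meta$spathe_orientation <- rec$spathe_orientation[i]
  dec$meta$relative_orientation <- relative_orientation(
    dec$meta$compass_orientation, dec$meta$spathe_orientation)
  dec$meta$alignment <- ifelse(
    dec$meta$relative_orientation %in% c(0L, 120L, 240L) ==
      (organ_type != "standard"), "expected", "rotated60")
  dec
}

orientation_labels <- function(decomp, groupby = c("compass", "relative")) {
  groupby <- match.arg(groupby)
  col <- paste0(switch(groupby, compass = "compass", relative = "relative"),
                "_orientation")
  if (is.null(decomp$meta[[col]]))
    stop("decomposition carries no ", col, " metadata", call. = FALSE)
  factor(decomp$meta[[col]], levels = seq(0L, 300L, by = 60L))
}

#' Test shape differences among orientation groups of one organ type
#'
#' Runs the permutation test (Goodall's F and Pillai's trace) and the CVA
#' for one shape component of one organ type, grouped by compass or
#' relative orientation.
#'
#' @param decomp A [decompose_organ()] result.
#' @param component `"symmetric"` or `"asymmetric"`.
#' @param groupby `"compass"` or `"relative"`.
#' @param n_permutations,seed,unit Passed to [permutation_test()].
#' @return List with `sample` ([grouped_shape_sample()]), `test`
#'   ([permutation_test()]) and `cva` ([cva()]).
#' @export
orientation_shape_test <- function(decomp,
                                   component = c("symmetric", "asymmetric"),
                                   groupby = c("compass", "relative"),
                                   n_permutations = 10000L, seed = NULL,
                                   unit = c("organ", "flower")) {
  component <- match.arg(component)
  g <- droplevels(orientation_labels(decomp, groupby))
  smp <- grouped_shape_sample(component_matrix(decomp, component), g,
                              component, flower_ids = decomp$meta$flower_id)
  list(sample = smp,
       test = permutation_test(smp, statistic = c("goodall_f", "pillai"),
                               n_permutations = n_permutations, seed = seed,
                               unit = unit),
       cva = cva(smp))
}

#' Null-calibration and power simulation of the orientation tests
#'
#' Repeatedly generates datasets from `params`, decomposes one organ type,
#' and records the permutation-test p-values (Goodall's F and Pillai's
#' trace) for one shape component and grouping. With all directional fields
#' zeroed this measures the empirical type-I error; with a compass field
#' injected it measures power.
#'
#' @param params [simulation_params()] describing one replicate dataset
#'   (its `seed` is overridden per replicate).
#' @param n_datasets Number of replicate datasets.
#' @param organ_type Organ type analyzed (default falls).
#' @param component Shape component tested.
#' @param groupby Grouping factor.
#' @param n_permutations Permutation iterations per replicate (default 199).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param unit Exchangeable unit for the permutations.
#' @return Data frame with one row per replicate: `rep`, `p_goodall`,
#'   `p_pillai`.
#' @export
simulate_pvalues <- function(params, n_datasets,
                             organ_type = "fall",
                             component = c("symmetric", "asymmetric"),
                             groupby = c("compass", "relative"),
                             n_permutations = 199L, seed = NULL,
                             unit = c("organ", "flower")) {
  component <- match.arg(component)
  groupby <- match.arg(groupby)
  seeds <- derive_seeds(seed, 2L * n_datasets)
  p <- matrix(NA_real_, n_datasets, 2L)
  for (i in seq_len(n_datasets)) {
    params$seed <- seeds[i]
    ds <- generate_dataset(params)
    dec <- decompose_organ(ds, organ_type)
    res <- orientation_shape_test(dec, component, groupby,
                                  n_permutations = n_permutations,
                                  seed = seeds[n_datasets + i], unit = unit)
    p[i, ] <- res$test$results$p_value[
      match(c("goodall_f", "pillai"), res$test$results$statistic)]
  }
  data.frame(rep = seq_len(n_datasets), p_goodall = p[, 1L],
             p_pillai = p[, 2L])
}
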