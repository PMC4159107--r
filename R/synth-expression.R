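#' Configuration for the synthetic expression generator
#'
#' Describes a class-conditional Gaussian expression study with a small set
#' of phase-informative probes, noisy redundant copies of those probes, and
#' a large background of uninformative probes.  The defaults emulate the
#' shape of a three-phase prostate-cancer cohort (77 normal, 66 primary
#' tumor, 24 metastatic samples) at desk scale: 4 informative probes, 2
#' redundant copies each, and 188 null probes (200 probes total).
#'
#' Each informative probe is assigned a direction (up- or down-regulated)
#' and an onset phase: its class mean is flat up to the onset class and then
#' changes by `effect_size` within-class standard deviations per class step.
#' The per-probe mean profile is therefore monotone in the phase ordering
#' (so the ordinal label correlation carries the signal) while the class
#' mean vectors are non-collinear (so the cosine sample distance can
#' separate the phases).
#'
#' @param n_samples_per_class named integer vector of per-class sample
#'   counts; names give the class order (first = baseline phase).
#' @param n_informative number of phase-informative probes.
#' @param n_redundant_per_informative noisy copies generated per
#'   informative probe.
#' @param n_null number of label-independent background probes.
#' @param effect_size class-mean shift per class step after onset, in units
#'   of the within-class standard deviation (which is 1).
#' @param redundancy_noise_sd standard deviation of the independent
#'   Gaussian noise added to each redundant copy; 0 gives exact duplicates.
#' @param baseline_range range of the per-probe baseline mean, drawn
#'   uniformly; expression values are on an arbitrary continuous scale.
#' @param seed integer random seed; identical config + seed reproduces the
#'   dataset exactly.
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_samples_per_class = c(NT = 77, PT = 66, MT = 24),
                                  n_informative = 4,
                                  n_redundant_per_informative = 2,
                                  n_null = 188,
                                  effect_size = 3,
                                  redundancy_noise_sd = 0.1,
                                  baseline_range = c(6, 12),
                                  seed = 1L) {
  if (is.null(names(n_samples_per_class)) || anyDuplicated(names(n_samples_per_class)))
    stop("n_samples_per_class must have unique class names")
  if (any(n_samples_per_class < 1))
    stop("every requested class must have at least one sample")
  counts <- c(n_informative, n_redundant_per_informative, n_null)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("probe counts must be nonnegative integers")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (redundancy_noise_sd < 0) stop("redundancy_noise_sd must be >= 0")
  structure(
    list(n_samples_per_class = n_samples_per_class,
         n_informative = as.integer(n_informative),
         n_redundant_per_informative = as.integer(n_redundant_per_informative),
         n_null = as.integer(n_null),
         effect_size = effect_size,
         redundancy_noise_sd = redundancy_noise_sd,
         baseline_range = baseline_range,
         seed = as.integer(seed)),
    class = "expression_sim_config")
}

#' Simulate a labeled expression dataset with known ground truth
#'
#' Draws a class-conditional Gaussian expression matrix as described in
#' [expression_sim_config()] and returns it together with a probe-role
#' sidecar table, so downstream feature selection can be checked against
#' the planted truth.
#'
#' Informative probes cycle through the four (direction, onset) marker
#' types: up at the second phase, down at the second phase, up at the last
#' phase, down at the last phase (onsets cycle over all non-baseline
#' phases when there are more than three classes).  Redundant probes are
#' their parent probe plus independent `N(0, redundancy_noise_sd^2)` noise.
#' Null probes are iid Gaussian around a per-probe baseline, independent of
#' the label.  Within-class standard deviation is 1 for every probe, so
#' `effect_size` is in sd units.
#'
#' @param config an [expression_sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{a [labeled_expression_matrix()]}
#'     \item{truth}{data.frame with columns `probe_id`, `role`
#'       (`"informative"`, `"redundant"`, `"null"`), `parent` (the
#'       informative probe a redundant copy duplicates, else `NA`),
#'       `direction` (+1/-1), `onset` (1-based non-baseline class step,
#'       `NA` for null probes)}
#'     \item{config}{the config used}
#'   }
#' @examples
#' sim <- simulate_expression_dataset(
#'   expression_sim_config(n_samples_per_class = c(A = 10, B = 10, C = 5),
#'                         n_null = 20, seed = 7))
#' table(sim$truth$role)
#' @export
simulate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  cls <- names(config$n_samples_per_class)
  n_cls <- length(cls)
  labels <- rep(cls, times = config$n_samples_per_class)
  n <- length(labels)
  phase <- rep(seq_len(n_cls) - 1L, times = config$n_samples_per_class)

  p_inf <- config$n_informative
  p_red <- p_inf * config$n_redundant_per_informative
  p_null <- config$n_null
  p_tot <- p_inf + p_red + p_null
  if (p_tot == 0L) stop("configuration produces zero probes")

  probe_ids <- sprintf("probe_%04d", seq_len(p_tot))
  sample_ids <- sprintf("S%03d", seq_len(n))

  # marker types: (direction, onset) cycled over informative probes;
  # onset k means the mean starts moving at class step k (1-based)
  onsets <- if (n_cls > 1) seq_len(n_cls - 1L) else integer(0)
  types <- expand.grid(direction = c(1, -1), onset = onsets)

  values <- matrix(NA_real_, nrow = p_tot, ncol = n,
                   dimnames = list(probe_ids, sample_ids))
  truth <- data.frame(probe_id = probe_ids,
                      role = rep(c("informative", "redundant", "null"),
                                 times = c(p_inf, p_red, p_null)),
                      parent = NA_character_,
                      direction = NA_real_,
                      onset = NA_integer_,
                      stringsAsFactors = FALSE)

  baseline <- stats::runif(p_tot, config$baseline_range[1], config$baseline_range[2])
  row <- 0L
  for (j in seq_len(p_inf)) {
    row <- row + 1L
    ty <- types[(j - 1L) %% nrow(types) + 1L, ]
    shift <- ty$direction * config$effect_size * pmax(0, phase - ty$onset + 1L)
    values[row, ] <- baseline[row] + shift + stats::rnorm(n)
    truth$direction[row] <- ty$direction
    truth$onset[row] <- as.integer(ty$onset)
  }
  for (j in seq_len(p_inf)) {
    for (r in seq_len(config$n_redundant_per_informative)) {
      row <- row + 1L
      values[row, ] <- values[j, ] +
        stats::rnorm(n, sd = config$redundancy_noise_sd)
      truth$parent[row] <- probe_ids[j]
      truth$direction[row] <- truth$direction[j]
      truth$onset[row] <- truth$onset[j]
    }
  }
  if (p_null > 0) {
    idx <- row + seq_len(p_null)
    values[idx, ] <- baseline[idx] +
      matrix(stats::rnorm(p_null * n), nrow = p_null)
  }

  list(matrix = labeled_expression_matrix(values, labels, class_order = cls),
       truth = truth,
       config = config)
}
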