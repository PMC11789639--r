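#' Configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters used by all `simulate_*` generators.
#' Defaults describe the study conditions the analyses are designed around:
#' a 14-species therian-like tree, a fractional expression increment of 0.26
#' per added X, an Xi/Xa allelic ratio of 0.55, the seven-point labeling
#' time course (0-7 h) with a half-life of 1.3 h, and a 2-guide x 3-culture
#' knockdown design with strong (80%) knockdown and full compensation.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param tree_n_leaves number of species in simulated trees.
#' @param loss_rate per-million-year hazard of irreversible gene loss on a
#'   branch (Dollo process), `>= 0`.
#' @param e_xa baseline expression (TPM) of the X-homolog at one active X.
#' @param rel_y expression of the Y-homolog relative to `e_xa` (the Y member
#'   of a pair is typically the lower-expressed homolog).
#' @param delta_ex_true fractional expression increment of the X-homolog per
#'   added X chromosome, relative to one active X.
#' @param delta_ey_true fractional increment of the Y-homolog per added Y.
#' @param coupling_k dimensionless strength of negative cross-regulation
#'   between the homologs (0 = independent).
#' @param ar_true true Xi/Xa transcript ratio, `>= 0`.
#' @param depth allele-count sampling depth per sample, `>= 1`.
#' @param alpha_true synthesis-scale parameter of the labeling model
#'   (normalized units per hour); default `beta_true`, i.e. plateau 1.
#' @param beta_true mRNA turnover rate in 1/h, `> 0`. Default corresponds to
#'   a 1.3 h half-life.
#' @param timepoints labeling collection times in hours.
#' @param total_tpm steady-state total TPM of the labeled transcript.
#' @param spike_tpm nominal TPM of the labeled spike-in control.
#' @param spike_drift_cv coefficient of variation of the per-library
#'   pulldown-scale drift the spike-in channel tracks.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise on TPM values.
#' @param kd_efficiency fraction of the targeted transcript removed by
#'   knockdown, in `[0, 1]`.
#' @param compensation_c fraction of the lost homolog's expression restored
#'   on the other homolog, `>= 0` (1 = full compensation).
#' @param n_control_genes number of unlinked control genes (no copy-number
#'   dependence) emitted alongside the homolog pair.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 7, noise_cv = 0)
#' cfg$delta_ex_true
#' @export
sim_config <- function(seed = 1L,
                       tree_n_leaves = 14L,
                       loss_rate = 0.001,
                       e_xa = 100,
                       rel_y = 0.5,
                       delta_ex_true = 0.26,
                       delta_ey_true = 0.26,
                       coupling_k = 0.15,
                       ar_true = 0.55,
                       depth = 1e5,
                       alpha_true = NULL,
                       beta_true = log(2) / 1.3,
                       timepoints = c(0, 0.5, 1, 1.5, 2, 3.5, 7),
                       total_tpm = 100,
                       spike_tpm = 50,
                       spike_drift_cv = 0.2,
                       noise_cv = 0.1,
                       kd_efficiency = 0.8,
                       compensation_c = 1,
                       n_control_genes = 20L) {
  .check_scalar(seed, "seed")
  .check_scalar(tree_n_leaves, "tree_n_leaves", lower = 2)
  .check_scalar(loss_rate, "loss_rate", lower = 0, allow_inf = TRUE)
  .check_scalar(e_xa, "e_xa", lower = 0)
  .check_scalar(rel_y, "rel_y", lower = 0)
  .check_scalar(delta_ex_true, "delta_ex_true")
  .check_scalar(delta_ey_true, "delta_ey_true")
  .check_scalar(coupling_k, "coupling_k", lower = 0)
  .check_scalar(ar_true, "ar_true", lower = 0)
  .check_scalar(depth, "depth", lower = 1)
  .check_scalar(beta_true, "beta_true", lower = .Machine$double.eps)
  if (is.null(alpha_true)) alpha_true <- beta_true
  .check_scalar(alpha_true, "alpha_true", lower = .Machine$double.eps)
  if (!is.numeric(timepoints) || any(is.na(timepoints)) ||
      any(timepoints < 0) || length(timepoints) < 2)
    stop("timepoints must be >= 2 nonnegative hours", call. = FALSE)
  .check_scalar(total_tpm, "total_tpm", lower = 0)
  .check_scalar(spike_tpm, "spike_tpm", lower = .Machine$double.eps)
  .check_scalar(spike_drift_cv, "spike_drift_cv", lower = 0)
  .check_scalar(noise_cv, "noise_cv", lower = 0)
  .check_scalar(kd_efficiency, "kd_efficiency", lower = 0, upper = 1)
  .check_scalar(compensation_c, "compensation_c", lower = 0)
  .check_scalar(n_control_genes, "n_control_genes", lower = 0)

  structure(list(
    seed = as.integer(seed),
    tree_n_leaves = as.integer(tree_n_leaves),
    loss_rate = loss_rate,
    e_xa = e_xa,
    rel_y = rel_y,
    delta_ex_true = delta_ex_true,
    delta_ey_true = delta_ey_true,
    coupling_k = coupling_k,
    ar_true = ar_true,
    depth = depth,
    alpha_true = alpha_true,
    beta_true = beta_true,
    timepoints = as.numeric(timepoints),
    total_tpm = total_tpm,
    spike_tpm = spike_tpm,
    spike_drift_cv = spike_drift_cv,
    noise_cv = noise_cv,
    kd_efficiency = kd_efficiency,
    compensation_c = compensation_c,
    n_control_genes = as.integer(n_control_genes)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (synthetic-data ground truth)\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
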