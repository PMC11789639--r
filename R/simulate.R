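#' Simulate irreversible (Dollo) gene loss on a species tree
#'
#' Each gene is present at the root and is lost independently on every branch
#' with probability `1 - exp(-loss_rate * branch_length)`. Loss is
#' irreversible: once lost on a branch, the gene is absent from all
#' descendants. This emulates the decay of Y-linked genes across a species
#' phylogeny.
#'
#' @param tree a rooted `phylo` tree with nonnegative branch lengths in
#'   millions of years.
#' @param loss_rate per-MY loss hazard, `>= 0` (`Inf` allowed: certain loss
#'   on any branch of positive length).
#' @param n_genes number of independent genes to simulate.
#' @param seed optional integer seed.
#'
#' @return Logical matrix of dimension `n_genes x n_leaves` (rownames
#'   `gene_1 ...`, colnames = tip labels): `TRUE` where the gene survives in
#'   that species.
#' @examples
#' tr <- ape::read.tree(text = "((A:100,B:100):50,(C:80,D:80):70):0;")
#' pres <- simulate_gene_loss(tr, loss_rate = 0.002, n_genes = 5, seed = 1)
#' @export
simulate_gene_loss <- function(tree, loss_rate, n_genes, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(loss_rate) || length(loss_rate) != 1L || is.na(loss_rate) ||
      loss_rate < 0)
    stop("loss_rate must be a single nonnegative number", call. = FALSE)
  .check_scalar(n_genes, "n_genes", lower = 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry nonnegative branch lengths", call. = FALSE)
  .maybe_seed(seed)

  # cladewise order lists each edge after the edge leading to its parent,
  # so parent states are always available when a child is visited
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- ntip + 1L
  n_genes <- as.integer(n_genes)

  p_loss <- 1 - exp(-loss_rate * tr$edge.length)
  p_loss[is.nan(p_loss)] <- 0  # Inf * 0 branch: no time to be lost

  state <- matrix(FALSE, nrow = n_genes, ncol = ntip + nnode)
  state[, root] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]
    child <- tr$edge[e, 2L]
    lost <- stats::runif(n_genes) < p_loss[e]
    state[, child] <- state[, parent] & !lost
  }
  presence <- state[, seq_len(ntip), drop = FALSE]
  dimnames(presence) <- list(paste0("gene_", seq_len(n_genes)), tr$tip.label)
  presence
}

# default karyotype grid: the fibroblast/LCL sex-chromosome series
.default_karyotypes <- function() {
  data.frame(
    nX = c(1, 1, 2, 3, 4, 2, 3, 1, 1, 1),
    nY = c(0, 1, 1, 1, 1, 0, 0, 2, 3, 4)
  )
}

#' Simulate expression across sex-chromosome aneuploidies
#'
#' Generates TPM observations for an X/Y homolog pair and unlinked control
#' genes across a grid of karyotypes. The noiseless X-homolog mean is
#' `e_xa * (1 + delta_ex_true * (nX - 1)) / (1 + coupling_k * nY * rel_y)`,
#' i.e. linear in X copy number with multiplicative repression by Y dosage;
#' the Y-homolog is symmetric (baseline `e_xa * rel_y`, repressed by
#' `coupling_k * nX`), and is zero when no Y is present. Observed values are
#' the means times mean-1 log-normal noise with coefficient of variation
#' `noise_cv`. Control genes have no copy-number dependence.
#'
#' @param config a [sim_config()].
#' @param karyotypes data.frame with integer columns `nX` (`>= 1`) and `nY`
#'   (`>= 0`), optionally `n21` (defaults to 2). Default: the ten-karyotype
#'   grid (1,0) ... (1,4).
#' @param n_per_karyotype samples per karyotype.
#' @param seed optional seed (default `config$seed`).
#'
#' @return List with `metadata` (sample, nX, nY, n21, cell_type, condition),
#'   `tpm` (gene x sample matrix; genes `homX`, `homY`, `ctrl_*`) and
#'   `truth` (the noiseless means per karyotype).
#' @export
simulate_aneuploidy_expression <- function(config,
                                           karyotypes = .default_karyotypes(),
                                           n_per_karyotype = 6,
                                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.matrix(karyotypes)) karyotypes <- as.data.frame(karyotypes)
  if (!is.data.frame(karyotypes) || nrow(karyotypes) == 0)
    stop("karyotypes must be a non-empty data.frame with nX, nY", call. = FALSE)
  if (!all(c("nX", "nY") %in% names(karyotypes)))
    stop("karyotypes needs columns nX and nY", call. = FALSE)
  if (any(karyotypes$nX < 1) || any(karyotypes$nY < 0))
    stop("karyotypes require nX >= 1 and nY >= 0", call. = FALSE)
  .check_scalar(n_per_karyotype, "n_per_karyotype", lower = 1)
  if (is.null(karyotypes$n21)) karyotypes$n21 <- 2L
  .maybe_seed(seed)

  k <- karyotypes[rep(seq_len(nrow(karyotypes)), each = n_per_karyotype), ,
                  drop = FALSE]
  n <- nrow(k)
  meta <- data.frame(
    sample = sprintf("s%03d", seq_len(n)),
    nX = as.integer(k$nX), nY = as.integer(k$nY), n21 = as.integer(k$n21),
    cell_type = "fibroblast", condition = "aneuploidy_series",
    stringsAsFactors = FALSE
  )

  mx <- config$e_xa * (1 + config$delta_ex_true * (meta$nX - 1)) /
    (1 + config$coupling_k * meta$nY * config$rel_y)
  my <- ifelse(meta$nY == 0, 0,
               config$e_xa * config$rel_y *
                 (1 + config$delta_ey_true * (meta$nY - 1)) /
                 (1 + config$coupling_k * meta$nX))

  ngenes <- 2L + config$n_control_genes
  gene_ids <- c("homX", "homY",
                if (config$n_control_genes > 0)
                  sprintf("ctrl_%02d", seq_len(config$n_control_genes)))
  tpm <- matrix(NA_real_, nrow = ngenes, ncol = n,
                dimnames = list(gene_ids, meta$sample))
  tpm["homX", ] <- mx * .lnorm_noise(n, config$noise_cv)
  tpm["homY", ] <- my * .lnorm_noise(n, config$noise_cv)
  if (config$n_control_genes > 0) {
    # per-gene baseline spread around e_xa, but flat in copy number
    ctrl_means <- config$e_xa * exp(stats::rnorm(config$n_control_genes, 0, 0.5))
    for (g in seq_len(config$n_control_genes))
      tpm[2L + g, ] <- ctrl_means[g] * .lnorm_noise(n, config$noise_cv)
  }

  list(metadata = meta, tpm = tpm,
       truth = list(mean_x = mx, mean_y = my,
                    delta_ex_true = config$delta_ex_true,
                    delta_ey_true = config$delta_ey_true,
                    coupling_k = config$coupling_k))
}

#' Simulate allele-specific read counts for an Xi/Xa-expressed gene
#'
#' Per sample, Xi-derived reads are binomial with success probability
#' `ar_true / (1 + ar_true)` at the given depth; Xa reads are the remainder.
#'
#' @param ar_true true Xi/Xa transcript ratio, `>= 0`.
#' @param depth total informative reads per sample, `>= 1`.
#' @param n_samples number of samples.
#' @param seed optional seed.
#' @return data.frame with columns `sample`, `xi_reads`, `xa_reads`.
#' @examples
#' simulate_allelic_counts(ar_true = 0.55, depth = 1000, n_samples = 3, seed = 1)
#' @export
simulate_allelic_counts <- function(ar_true, depth, n_samples, seed = NULL) {
  if (!is.numeric(ar_true) || length(ar_true) != 1L || is.na(ar_true) ||
      ar_true < 0)
    stop("ar_true must be a single nonnegative number", call. = FALSE)
  .check_scalar(depth, "depth", lower = 1)
  .check_scalar(n_samples, "n_samples", lower = 1)
  .maybe_seed(seed)
  depth <- as.integer(round(depth))
  n_samples <- as.integer(n_samples)
  p_xi <- ar_true / (1 + ar_true)
  xi <- stats::rbinom(n_samples, size = depth, prob = p_xi)
  data.frame(sample = sprintf("s%03d", seq_len(n_samples)),
             xi_reads = xi, xa_reads = depth - xi,
             stringsAsFactors = FALSE)
}

#' Simulate a metabolic-labeling time course
#'
#' Nascent-RNA labeling with first-order turnover: the noiseless normalized
#' fraction is `y(t) = (alpha/beta) * (1 - exp(-beta * t))` (plateau
#' `alpha/beta`, half the plateau reached at `t = ln2/beta`). Each library
#' (time point x replicate) carries a multiplicative pulldown-scale drift
#' that affects the nascent and spike-in channels identically, so spike-in
#' normalization is required to recover `y(t)`; log-normal measurement noise
#' (`noise_cv`) is applied independently per channel.
#'
#' @param config a [sim_config()]; uses `alpha_true`, `beta_true`,
#'   `timepoints`, `total_tpm`, `spike_tpm`, `spike_drift_cv`, `noise_cv`.
#' @param n_replicates replicate time courses.
#' @param seed optional seed (default `config$seed`).
#' @return data.frame with columns `time_h`, `replicate`, `nascent_tpm`,
#'   `total_tpm`, `spike_tpm`, `y_true` (the noiseless normalized fraction).
#' @export
simulate_labeling_timecourse <- function(config, n_replicates = 1,
                                         seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$beta_true <= 0)
    stop("beta_true must be positive", call. = FALSE)
  .check_scalar(n_replicates, "n_replicates", lower = 1)
  .maybe_seed(seed)

  tt <- rep(config$timepoints, times = n_replicates)
  rep_id <- rep(seq_len(n_replicates), each = length(config$timepoints))
  n <- length(tt)
  y <- (config$alpha_true / config$beta_true) * (1 - exp(-config$beta_true * tt))

  drift <- if (config$spike_drift_cv > 0)
    .lnorm_noise(n, config$spike_drift_cv) else rep(1, n)
  nascent <- y * config$total_tpm * drift * .lnorm_noise(n, config$noise_cv)
  total <- config$total_tpm * .lnorm_noise(n, config$noise_cv)
  spike <- config$spike_tpm * drift * .lnorm_noise(n, config$noise_cv)

  data.frame(time_h = tt, replicate = rep_id,
             nascent_tpm = nascent, total_tpm = total, spike_tpm = spike,
             y_true = y)
}

#' Simulate a homolog knockdown experiment
#'
#' Three conditions (`control`, `kdX`, `kdY`) across guides and replicate
#' cultures. In `kdX` the X-homolog mean is scaled by
#' `1 - kd_efficiency` and the Y-homolog gains `compensation_c` times the
#' lost X expression (symmetrically for `kdY`); mean-1 log-normal noise with
#' coefficient of variation `noise_cv` is applied to each observation.
#'
#' @param config a [sim_config()].
#' @param n_guides guides per condition, `>= 1`.
#' @param n_replicates replicate cultures per guide, `>= 1`.
#' @param seed optional seed (default `config$seed`).
#' @return data.frame with columns `condition`, `guide`, `replicate`,
#'   `tpm_x`, `tpm_y`, `summed`.
#' @export
simulate_knockdown <- function(config, n_guides = 2, n_replicates = 3,
                               seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .check_scalar(n_guides, "n_guides", lower = 1)
  .check_scalar(n_replicates, "n_replicates", lower = 1)
  .maybe_seed(seed)

  mx <- config$e_xa
  my <- config$e_xa * config$rel_y
  eff <- config$kd_efficiency
  cc <- config$compensation_c
  means <- list(
    control = c(x = mx, y = my),
    kdX = c(x = mx * (1 - eff), y = my + cc * eff * mx),
    kdY = c(x = mx + cc * eff * my, y = my * (1 - eff))
  )

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      guide = seq_len(n_guides),
                      condition = names(means),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  mu_x <- vapply(grid$condition, function(cn) means[[cn]]["x"], 0)
  mu_y <- vapply(grid$condition, function(cn) means[[cn]]["y"], 0)
  out <- data.frame(
    condition = grid$condition,
    guide = paste0("g", grid$guide),
    replicate = grid$replicate,
    tpm_x = mu_x * .lnorm_noise(n, config$noise_cv),
    tpm_y = mu_y * .lnorm_noise(n, config$noise_cv),
    stringsAsFactors = FALSE
  )
  out$summed <- out$tpm_x + out$tpm_y
  rownames(out) <- NULL
  out
}

#' Simulate a relative-quantification qPCR experiment
#'
#' A fold change `f` of the target transcript is implemented as a shift of
#' `-log2(f)` in the target Ct; Gaussian noise of standard deviation
#' `noise_sd` cycles is added to both target and reference Ct values.
#'
#' @param fold_changes positive numeric vector of true expression fold
#'   changes relative to control, named by dose (or time) label; the first
#'   element is taken as the control level when `control_label` is not set
#'   downstream.
#' @param ct_ref_mean mean reference-gene Ct (cycles).
#' @param noise_sd Gaussian Ct noise (cycles); 0 gives a noiseless run.
#' @param n_reps replicates per dose.
#' @param seed optional seed.
#' @param delta_ct_base true control `Ct_target - Ct_ref` (cycles).
#' @return data.frame with columns `sample`, `dose`, `ct_target`, `ct_ref`.
#' @examples
#' simulate_qpcr(c(`0` = 1, `10` = 2.5), noise_sd = 0, n_reps = 2, seed = 1)
#' @export
simulate_qpcr <- function(fold_changes, ct_ref_mean = 20, noise_sd = 0.05,
                          n_reps = 3, seed = NULL, delta_ct_base = 5) {
  if (!is.numeric(fold_changes) || length(fold_changes) < 1 ||
      any(is.na(fold_changes)) || any(fold_changes <= 0))
    stop("fold_changes must be positive", call. = FALSE)
  .check_scalar(ct_ref_mean, "ct_ref_mean")
  .check_scalar(noise_sd, "noise_sd", lower = 0)
  .check_scalar(n_reps, "n_reps", lower = 1)
  .maybe_seed(seed)
  doses <- names(fold_changes)
  if (is.null(doses)) doses <- as.character(seq_along(fold_changes) - 1L)

  n_reps <- as.integer(n_reps)
  n <- length(fold_changes) * n_reps
  dose <- rep(doses, each = n_reps)
  f <- rep(fold_changes, each = n_reps)
  ct_ref <- ct_ref_mean + stats::rnorm(n, 0, noise_sd)
  ct_target <- ct_ref_mean + delta_ct_base - log2(f) + stats::rnorm(n, 0, noise_sd)
  data.frame(sample = sprintf("s%03d", seq_len(n)), dose = dose,
             ct_target = ct_target, ct_ref = ct_ref,
             stringsAsFactors = FALSE)
}
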