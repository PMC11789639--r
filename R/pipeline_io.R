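#' Read a gene x sample expression table
#'
#' Tab-separated file with a header row of sample ids and gene ids in the
#' first column. Duplicate gene ids are rejected; any non-numeric cell is an
#' error reported with its row and column; missing cells are kept as `NA`
#' and counted in a message.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression table needs a gene column plus >= 1 sample column",
         call. = FALSE)
  genes <- df[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                dimnames = list(genes, names(df)[-1L]))
  for (j in seq_len(ncol(mat))) {
    cell <- df[[j + 1L]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !empty)
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                   cell[bad[1L]], bad[1L], genes[bad[1L]],
                   colnames(mat)[j]), call. = FALSE)
    mat[, j] <- num
  }
  n_missing <- sum(is.na(mat))
  if (n_missing > 0)
    message(n_missing, " missing cell(s) read as NA")
  mat
}

#' Write a gene x sample expression table
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a karyotype string into chromosome counts
#'
#' Standard cytogenetic shorthand such as `"46,XY"`, `"45,X"` or
#' `"49,XYYYY"`: the digits before the comma give the total chromosome
#' count; the letters give the sex-chromosome constitution. Consistency
#' (44 autosomes + nX + nY = total) is checked.
#'
#' @param karyotype character vector of karyotype strings.
#' @return data.frame with columns `karyotype`, `total`, `nX`, `nY`.
#' @examples
#' parse_karyotype(c("46,XY", "49,XYYYY", "45,X"))
#' @export
parse_karyotype <- function(karyotype) {
  karyotype <- as.character(karyotype)
  m <- regmatches(karyotype, regexec("^([0-9]+),([XY]+)$", karyotype))
  rows <- lapply(seq_along(karyotype), function(i) {
    g <- m[[i]]
    if (length(g) != 3L)
      stop("malformed karyotype string: '", karyotype[i], "'", call. = FALSE)
    total <- as.integer(g[2L])
    sex <- strsplit(g[3L], "")[[1L]]
    nX <- sum(sex == "X")
    nY <- sum(sex == "Y")
    if (44L + nX + nY != total)
      stop("karyotype '", karyotype[i], "' inconsistent: 44 autosomes + ",
           nX, " X + ", nY, " Y != ", total, call. = FALSE)
    data.frame(karyotype = karyotype[i], total = total, nX = nX, nY = nY,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a sample metadata table
#'
#' TSV with a `sample` column plus either integer columns `nX`/`nY` or a
#' `karyotype` column (parsed with [parse_karyotype()]; an error names the
#' offending sample). Optional columns `n21` (default 2), `cell_type` and
#' `condition` are carried through.
#'
#' @param path path to the TSV file.
#' @return Validated data.frame with columns `sample`, `nX`, `nY`, `n21`,
#'   and any extra columns present.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df))
    stop("metadata needs a 'sample' column", call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicated sample id(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  if (!all(c("nX", "nY") %in% names(df))) {
    if (!"karyotype" %in% names(df))
      stop("metadata needs nX/nY columns or a karyotype column",
           call. = FALSE)
    parsed <- lapply(seq_len(nrow(df)), function(i)
      tryCatch(parse_karyotype(df$karyotype[i]),
               error = function(e) stop("sample '", df$sample[i], "': ",
                                        conditionMessage(e), call. = FALSE)))
    parsed <- do.call(rbind, parsed)
    df$nX <- parsed$nX
    df$nY <- parsed$nY
  }
  if (any(is.na(df$nX)) || any(df$nX < 1) || any(df$nX != round(df$nX)))
    stop("nX must be a positive integer for every sample", call. = FALSE)
  if (any(is.na(df$nY)) || any(df$nY < 0) || any(df$nY != round(df$nY)))
    stop("nY must be a nonnegative integer for every sample", call. = FALSE)
  if (is.null(df$n21)) df$n21 <- 2L
  df
}

.pipeline_stages <- c("survival", "dosage", "allelic", "knockdown",
                      "qpcr", "decay")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates every input with [sim_config()] ground truth, runs the matching
#' analysis stage, writes per-stage TSV inputs and results plus a
#' reproducibility manifest (`manifest.json`: seed, configuration, package
#' version, ground-truth parameters) to `out_dir`, and returns all results.
#' Identical configurations and seeds produce identical bundles.
#'
#' @param config named list with keys `seed` (integer), `out_dir` (path),
#'   `stages` (subset of survival, dosage, allelic, knockdown, qpcr, decay;
#'   default all) and `sim` (named overrides for [sim_config()]); unknown
#'   keys anywhere are rejected. Alternatively a path to a YAML file with
#'   the same structure.
#' @return Invisible named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop("config must be a named list or a YAML path", call. = FALSE)
  known <- c("seed", "out_dir", "stages", "sim")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (is.null(out_dir))
    stop("config$out_dir is required", call. = FALSE)
  stages <- if (is.null(config$stages)) .pipeline_stages else config$stages
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sim_over <- if (is.null(config$sim)) list() else config$sim
  bad <- setdiff(names(sim_over), names(formals(sim_config)))
  if (length(bad))
    stop("unknown sim parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sim_over$seed <- seed
  cfg <- do.call(sim_config, sim_over)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()

  if ("survival" %in% stages) {
    set.seed(seed + 101L)
    tree <- ape::rtree(cfg$tree_n_leaves,
                       tip.label = sprintf("sp%02d", seq_len(cfg$tree_n_leaves)))
    tree$edge.length <- tree$edge.length * 100  # MY scale
    presence <- simulate_gene_loss(tree, cfg$loss_rate, n_genes = 50)
    tab <- survival_table(tree, presence)
    ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
    .write_tsv(data.frame(gene = rep(rownames(presence), ncol(presence)),
                          species = rep(colnames(presence),
                                        each = nrow(presence)),
                          present = as.integer(presence)),
               file.path(out_dir, "gene_presence.tsv"))
    .write_tsv(format_survival_table(tab),
               file.path(out_dir, "survival_table.tsv"))
    results$survival <- tab
  }

  if ("dosage" %in% stages) {
    sim <- simulate_aneuploidy_expression(cfg, seed = seed + 102L)
    .write_tsv(sim$metadata, file.path(out_dir, "aneuploidy_metadata.tsv"))
    write_expression_table(sim$tpm, file.path(out_dir, "aneuploidy_tpm.tsv"))
    fits <- rbind(
      dosage_fit_table(sim$metadata, sim$tpm, "homX", predictor = "nX"),
      dosage_fit_table(sim$metadata, sim$tpm, "homX", predictor = "nY"),
      dosage_fit_table(sim$metadata, sim$tpm, "homY", predictor = "nY"),
      dosage_fit_table(sim$metadata, sim$tpm, "homY", predictor = "nX")
    )
    .write_tsv(fits, file.path(out_dir, "dosage_fits.tsv"))
    results$dosage <- fits
  }

  if ("allelic" %in% stages) {
    counts <- simulate_allelic_counts(cfg$ar_true, cfg$depth, n_samples = 50,
                                      seed = seed + 103L)
    counts$ar <- allelic_ratio(counts$xi_reads, counts$xa_reads)
    test <- compare_ar_delta_e(counts$ar, cfg$delta_ex_true)
    .write_tsv(counts, file.path(out_dir, "allelic_counts.tsv"))
    .write_tsv(data.frame(mean_ar = test$mean_ar, delta_e = test$delta_e,
                          t_statistic = test$statistic, df = test$df,
                          p_value = test$p_value),
               file.path(out_dir, "ar_vs_delta_e.tsv"))
    results$allelic <- test
  }

  if ("knockdown" %in% stages) {
    kd <- simulate_knockdown(cfg, seed = seed + 104L)
    stats_tab <- compensation_anova(kd)
    .write_tsv(kd, file.path(out_dir, "knockdown.tsv"))
    .write_tsv(stats_tab, file.path(out_dir, "compensation_anova.tsv"))
    results$knockdown <- stats_tab
  }

  if ("qpcr" %in% stages) {
    folds <- c(`0` = 1, `1` = 1.2, `2` = 1.5, `5` = 2, `10` = 2.5)
    rec <- simulate_qpcr(folds, seed = seed + 105L)
    out <- qpcr_fold_change(rec, control_label = "0")
    .write_tsv(rec, file.path(out_dir, "qpcr_ct.tsv"))
    .write_tsv(out, file.path(out_dir, "qpcr_folds.tsv"))
    results$qpcr <- out
  }

  if ("decay" %in% stages) {
    tc <- simulate_labeling_timecourse(cfg, n_replicates = 2,
                                       seed = seed + 106L)
    fit <- fit_decay_timecourse(tc)
    .write_tsv(tc, file.path(out_dir, "labeling_timecourse.tsv"))
    .write_tsv(data.frame(alpha = fit$alpha, beta = fit$beta,
                          half_life_h = fit$half_life, plateau = fit$plateau,
                          rss = fit$rss, converged = fit$converged),
               file.path(out_dir, "decay_fit.tsv"))
    results$decay <- fit
  }

  manifest <- list(seed = seed, stages = stages,
                   package = "xybuffer",
                   version = as.character(utils::packageVersion("xybuffer")),
                   ground_truth = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
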