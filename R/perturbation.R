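#' Summed expression of an X-Y homolog pair
#'
#' @param tpm_x,tpm_y nonnegative TPM vectors (recycled).
#' @return Elementwise sum, the pair's combined transcript output.
#' @export
summed_pair_expression <- function(tpm_x, tpm_y) {
  if (!is.numeric(tpm_x) || !is.numeric(tpm_y) ||
      any(tpm_x < 0, na.rm = TRUE) || any(tpm_y < 0, na.rm = TRUE))
    stop("TPM values must be nonnegative", call. = FALSE)
  tpm_x + tpm_y
}

#' One-way ANOVA of knockdown compensation
#'
#' Tests, separately for the X-homolog, the Y-homolog, and their summed
#' expression, whether mean TPM differs across knockdown conditions. Full
#' compensation predicts a significant targeted-homolog channel with a
#' non-significant summed channel.
#'
#' @param kd_table data.frame with columns `condition`, `replicate`,
#'   `tpm_x`, `tpm_y` (and optionally `guide`, `summed`); see
#'   [simulate_knockdown()]. Guides are pooled within condition.
#' @param channels which response channels to test.
#' @return data.frame with one row per channel: `channel`, `df_between`,
#'   `df_within`, `f_statistic`, `p_value`.
#' @export
compensation_anova <- function(kd_table,
                               channels = c("tpm_x", "tpm_y", "summed")) {
  if (!is.data.frame(kd_table) ||
      !all(c("condition", "tpm_x", "tpm_y") %in% names(kd_table)))
    stop("kd_table needs columns condition, tpm_x, tpm_y", call. = FALSE)
  if (is.null(kd_table$summed))
    kd_table$summed <- summed_pair_expression(kd_table$tpm_x, kd_table$tpm_y)
  cond <- factor(kd_table$condition)
  if (nlevels(cond) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  counts <- table(cond)
  if (any(counts < 2L))
    stop("condition(s) with fewer than 2 replicates: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  channels <- match.arg(channels, several.ok = TRUE)
  rows <- lapply(channels, function(ch) {
    av <- stats::aov(kd_table[[ch]] ~ cond)
    s <- summary(av)[[1L]]
    data.frame(channel = ch, df_between = s[1L, "Df"],
               df_within = s[2L, "Df"], f_statistic = s[1L, "F value"],
               p_value = s[1L, "Pr(>F)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison (Mann-Whitney or Welch t)
#'
#' Two-sided comparison of two groups of expression values, as used for
#' deletion-versus-intact contrasts. Defaults to the Mann-Whitney U test;
#' Welch's t-test is available. Groups that are entirely tied across both
#' samples yield p = 1 with a warning.
#'
#' @param values_a,values_b numeric vectors (each `>= 2` observations).
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @return list with `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney", "t_test")) {
  test <- match.arg(test)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(statistic = NA_real_, p_value = 1, test = test))
  }
  if (test == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              alternative = "two.sided"))
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
  } else {
    ht <- stats::t.test(values_a, values_b, alternative = "two.sided")
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
  }
}

#' Relative qPCR quantification by delta-delta-Ct
#'
#' For each record, `delta_ct = ct_target - ct_ref`; for each treated dose,
#' `ddct` is the per-sample `delta_ct` minus the mean control `delta_ct`,
#' and the fold change is `2^(-mean(ddct))` (amplification efficiency fixed
#' at 2). Significance is a per-dose t-test of treated versus control
#' `delta_ct` values; the default one-sided alternative `"increase"` tests
#' for elevated target expression, i.e. decreased `delta_ct`.
#'
#' @param records data.frame with columns `dose` (or time label),
#'   `ct_target`, `ct_ref`; see [simulate_qpcr()]. Records with a missing
#'   reference Ct are dropped with a warning.
#' @param control_label value of `dose` identifying the control group.
#' @param alternative `"increase"` (default; expression up under treatment),
#'   `"decrease"`, or `"two.sided"`.
#' @return data.frame with one row per dose: `dose`, `n`, `mean_delta_ct`,
#'   `mean_ddct`, `fold`, `p_value` (NA for the control row).
#' @examples
#' rec <- simulate_qpcr(c(`0` = 1, `10` = 2), noise_sd = 0, n_reps = 3,
#'                      seed = 1)
#' qpcr_fold_change(rec, control_label = "0")
#' @export
qpcr_fold_change <- function(records, control_label,
                             alternative = c("increase", "decrease",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  need <- c("dose", "ct_target", "ct_ref")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  drop <- is.na(records$ct_ref) | is.na(records$ct_target)
  if (any(drop)) {
    warning(sum(drop), " record(s) with missing Ct dropped")
    records <- records[!drop, , drop = FALSE]
  }
  records$delta_ct <- records$ct_target - records$ct_ref
  is_control <- records$dose == control_label
  if (!any(is_control))
    stop("no control records with dose '", control_label, "'", call. = FALSE)
  dct0 <- records$delta_ct[is_control]
  side <- switch(alternative, increase = "less", decrease = "greater",
                 two.sided = "two.sided")
  doses <- unique(records$dose)
  rows <- lapply(doses, function(d) {
    dct <- records$delta_ct[records$dose == d]
    ddct <- dct - mean(dct0)
    p <- if (d == control_label) NA_real_
    else if (stats::sd(c(dct, dct0)) == 0 ||
             (stats::sd(dct) == 0 && stats::sd(dct0) == 0)) {
      # degenerate noiseless data: exact decision in the tested direction
      warning("zero Ct variance for dose '", d, "'; exact decision reported")
      shift <- mean(dct) - mean(dct0)
      switch(side,
             less = if (shift < 0) 0 else 1,
             greater = if (shift > 0) 0 else 1,
             two.sided = if (shift != 0) 0 else 1)
    } else stats::t.test(dct, dct0, alternative = side)$p.value
    data.frame(dose = d, n = length(dct), mean_delta_ct = mean(dct),
               mean_ddct = mean(ddct), fold = 2^(-mean(ddct)), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' intersection between two gene sets drawn from a common universe — the
#' standard enrichment test for overlap of differential-expression gene
#' lists.
#'
#' @param set_a,set_b character vectors of gene ids (duplicates removed).
#' @param universe_size number of genes in the universe (`>= |A union B|`).
#' @return list with `overlap`, `expected`, `p_value`.
#' @examples
#' gene_set_overlap(letters[1:10], letters[8:15], universe_size = 100)
#' @export
gene_set_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  .check_scalar(universe_size, "universe_size", lower = 1)
  k <- length(intersect(set_a, set_b))
  union_n <- length(set_a) + length(set_b) - k
  if (universe_size < union_n)
    stop("universe_size smaller than the union of the sets", call. = FALSE)
  m <- length(set_a)
  nn <- universe_size - m
  p <- stats::phyper(k - 1, m, nn, length(set_b), lower.tail = FALSE)
  list(overlap = k, expected = m * length(set_b) / universe_size,
       p_value = p)
}
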