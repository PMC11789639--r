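#' Percentile ranks oriented toward constraint
#'
#' Percent rank in `[0, 100]` with 100 = most constrained. For metrics where
#' low values indicate constraint (e.g. LOEUF) use
#' `orientation = "low_is_constrained"`; for metrics where high values do
#' (e.g. conserved-miRNA-targeting probability) use
#' `"high_is_constrained"`. Ties take the mid-rank; missing values propagate
#' as missing and do not enter the ranking.
#'
#' @param values numeric vector (>= 2 finite values required).
#' @param orientation which end of the metric means "constrained".
#' @return Numeric vector of percentiles in `[0, 100]`.
#' @examples
#' percentile_rank(c(0.1, 0.4, 0.9, 1.2), "low_is_constrained")
#' @export
percentile_rank <- function(values,
                            orientation = c("low_is_constrained",
                                            "high_is_constrained")) {
  orientation <- match.arg(orientation)
  if (!is.numeric(values))
    stop("values must be numeric", call. = FALSE)
  finite <- is.finite(values)
  n <- sum(finite)
  if (n < 2L)
    stop("need at least 2 finite values to rank", call. = FALSE)
  x <- values
  if (orientation == "low_is_constrained") x <- -x
  if (length(unique(x[finite])) == 1L)
    warning("all values identical; returning 50 for every gene")
  r <- rep(NA_real_, length(values))
  r[finite] <- rank(x[finite], ties.method = "average")
  (r - 1) / (n - 1) * 100
}

#' Pythagorean combination of two scores
#'
#' `sqrt(a^2 + b^2)`: the Euclidean norm of two nonnegative scores, used to
#' combine a constraint-on-overexpression percentile with a
#' constraint-on-loss percentile (or a human pair breadth with an outgroup
#' breadth) into one dosage-sensitivity metric.
#'
#' @param a,b nonnegative numeric vectors (recycled).
#' @return `sqrt(a^2 + b^2)`; missing inputs propagate.
#' @examples
#' pythagorean_combine(3, 4)  # 5
#' @export
pythagorean_combine <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b))
    stop("scores must be numeric", call. = FALSE)
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("scores must be nonnegative", call. = FALSE)
  sqrt(a^2 + b^2)
}

#' Tissue expression breadth
#'
#' `B = sum(TPM) / (max(TPM) * n_tissues)`: 1 for perfectly uniform
#' expression, `1/n_tissues` for expression confined to a single tissue.
#' Tissues with zero expression count toward `n_tissues`. Scale-invariant.
#'
#' @param tpm_by_tissue nonnegative TPM vector across tissues.
#' @param n_tissues number of tissues (default `length(tpm_by_tissue)`).
#' @return Breadth in `(0, 1]`, or `NA` with a warning for an all-zero gene.
#' @examples
#' expression_breadth(c(10, 5, 5))  # 20 / (10 * 3)
#' @export
expression_breadth <- function(tpm_by_tissue, n_tissues = length(tpm_by_tissue)) {
  if (!is.numeric(tpm_by_tissue) || any(is.na(tpm_by_tissue)) ||
      any(tpm_by_tissue < 0))
    stop("TPM values must be nonnegative and non-missing", call. = FALSE)
  .check_scalar(n_tissues, "n_tissues", lower = 1)
  m <- max(tpm_by_tissue)
  if (m == 0) {
    warning("gene not expressed in any tissue; breadth undefined")
    return(NA_real_)
  }
  sum(tpm_by_tissue) / (m * n_tissues)
}

#' Mean breadth of an X-Y homolog pair
#'
#' Arithmetic mean of the X- and Y-homolog expression breadths. When one
#' homolog's breadth is unavailable the other is returned with a warning
#' (some outgroup orthologs lack expression data).
#'
#' @param b_x,b_y breadths in `(0, 1]` (either may be `NA`).
#' @return Pair mean (vectorized).
#' @export
pair_breadth <- function(b_x, b_y) {
  if (!is.numeric(b_x) || !is.numeric(b_y))
    stop("breadths must be numeric", call. = FALSE)
  if (any(c(b_x, b_y) <= 0, na.rm = TRUE) || any(c(b_x, b_y) > 1, na.rm = TRUE))
    stop("breadths must lie in (0, 1]", call. = FALSE)
  out <- (b_x + b_y) / 2
  one_missing <- xor(is.na(b_x), is.na(b_y))
  if (any(one_missing)) {
    warning("one homolog breadth missing; returning the available value")
    out[one_missing] <- ifelse(is.na(b_x[one_missing]),
                               b_y[one_missing], b_x[one_missing])
  }
  out
}

#' Combined cross-species breadth score
#'
#' Pythagorean sum of the human pair breadth and the outgroup (e.g. chicken)
#' ortholog breadth; see [pythagorean_combine()].
#'
#' @param human_pair_breadth,outgroup_breadth breadth scores.
#' @return `sqrt(h^2 + o^2)`.
#' @export
combined_breadth <- function(human_pair_breadth, outgroup_breadth) {
  pythagorean_combine(human_pair_breadth, outgroup_breadth)
}

#' Constraint rank table
#'
#' Ranks genes by constraint on overexpression (conserved-miRNA-targeting
#' probability, high = constrained) and on loss of function (LOEUF, low =
#' constrained), applies the minimum-expected-LoF filter to the LOEUF
#' percentile, and combines the two percentiles by Pythagorean sum.
#'
#' @param metrics data.frame with columns `gene`, `pct`, `loeuf`,
#'   `expected_lof`.
#' @param min_expected_lof genes with fewer expected LoF variants than this
#'   carry no LOEUF percentile (default 10).
#' @param rank_within_filtered rank LOEUF among filtered genes only
#'   (default), or among all genes before blanking filtered ones.
#' @return data.frame with added `pct_percentile`, `loeuf_percentile`,
#'   `combined` columns, sorted by `combined` descending (NA last).
#' @export
constraint_rank_table <- function(metrics, min_expected_lof = 10,
                                  rank_within_filtered = TRUE) {
  need <- c("gene", "pct", "loeuf", "expected_lof")
  if (!is.data.frame(metrics) || !all(need %in% names(metrics)))
    stop("metrics must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- metrics
  out$pct_percentile <- percentile_rank(out$pct, "high_is_constrained")
  loeuf <- out$loeuf
  fails <- !is.na(out$expected_lof) & out$expected_lof < min_expected_lof
  if (rank_within_filtered) {
    loeuf[fails] <- NA_real_
    out$loeuf_percentile <- percentile_rank(loeuf, "low_is_constrained")
  } else {
    out$loeuf_percentile <- percentile_rank(loeuf, "low_is_constrained")
    out$loeuf_percentile[fails] <- NA_real_
  }
  out$combined <- pythagorean_combine(out$pct_percentile, out$loeuf_percentile)
  out <- out[order(-xtfrm(out$combined)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-species breadth table for X-Y gene pairs
#'
#' Computes per-gene expression breadth from gene x tissue TPM matrices for
#' human X- and Y-homologs and an outgroup ortholog, the pair mean, and the
#' combined cross-species score.
#'
#' @param human_tpm gene x tissue TPM matrix (human).
#' @param outgroup_tpm gene x tissue TPM matrix (outgroup species).
#' @param pairs data.frame with columns `pair`, `gene_x`, `gene_y`,
#'   `outgroup_gene`.
#' @return data.frame with per-homolog breadths, `pair_breadth`,
#'   `outgroup_breadth` and `combined_breadth`, sorted by the combined score.
#' @export
breadth_table <- function(human_tpm, outgroup_tpm, pairs) {
  need <- c("pair", "gene_x", "gene_y", "outgroup_gene")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  b_of <- function(mat, gene) {
    if (is.na(gene) || !gene %in% rownames(mat)) return(NA_real_)
    expression_breadth(mat[gene, ])
  }
  b_x <- vapply(pairs$gene_x, b_of, 0, mat = human_tpm)
  b_y <- vapply(pairs$gene_y, b_of, 0, mat = human_tpm)
  b_o <- vapply(pairs$outgroup_gene, b_of, 0, mat = outgroup_tpm)
  pb <- pair_breadth(b_x, b_y)
  out <- data.frame(pair = pairs$pair, breadth_x = b_x, breadth_y = b_y,
                    pair_breadth = pb, outgroup_breadth = b_o,
                    combined_breadth = combined_breadth(pb, b_o),
                    stringsAsFactors = FALSE)
  out <- out[order(-xtfrm(out$combined_breadth)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
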