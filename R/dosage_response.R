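# baseline (single-copy) chromosome count at which delta_e is referenced:
# one active X, one Y (a 46,XY cell), two copies of chromosome 21
.baseline_count <- c(nX = 1, nY = 1, n21 = 2)

#' Fit a dosage response of expression on chromosome copy number
#'
#' Ordinary least-squares regression of TPM on the chosen chromosome count,
#' with Pearson correlation and its two-sided p-value. The baseline is the
#' fitted expression at the natural single-copy count (nX = 1, nY = 1,
#' n21 = 2), and `delta_e` — the fractional change in expression per added
#' chromosome, relative to baseline — is `slope / baseline`.
#'
#' @param metadata data.frame with columns `sample` and the predictor
#'   (`nX`, `nY` or `n21`).
#' @param tpm gene x sample TPM matrix (colnames matching
#'   `metadata$sample`), or a numeric vector of per-sample TPM for one gene.
#' @param gene gene id (row of `tpm`); ignored when `tpm` is a vector.
#' @param predictor one of `"nX"`, `"nY"`, `"n21"`.
#' @return An object of class `"dosage_fit"`: list with `gene`, `predictor`,
#'   `slope`, `intercept`, `baseline_count`, `baseline`, `pearson_r`,
#'   `p_value`, `delta_e`, `n`.
#' @examples
#' meta <- data.frame(sample = c("a", "b", "c", "d"), nY = c(0, 1, 2, 3))
#' fit_dosage_response(meta, c(100, 90, 80, 70), predictor = "nY")
#' @export
fit_dosage_response <- function(metadata, tpm, gene = NULL,
                                predictor = c("nX", "nY", "n21")) {
  predictor <- match.arg(predictor)
  if (!is.data.frame(metadata) || !predictor %in% names(metadata))
    stop("metadata must contain column '", predictor, "'", call. = FALSE)
  x <- as.numeric(metadata[[predictor]])
  if (is.matrix(tpm)) {
    if (is.null(gene) || !gene %in% rownames(tpm))
      stop("gene not found in tpm matrix", call. = FALSE)
    if (!is.null(metadata$sample) && !is.null(colnames(tpm)))
      y <- tpm[gene, match(metadata$sample, colnames(tpm))]
    else y <- tpm[gene, ]
  } else {
    y <- as.numeric(tpm)
  }
  if (length(x) != length(y))
    stop("metadata and expression vector lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 samples", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("no dosage contrast: predictor '", predictor, "' is constant",
         call. = FALSE)

  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (stats::var(y) == 0) {
    warning("constant response; correlation reported as 0")
    r <- 0; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  x0 <- .baseline_count[[predictor]]
  baseline <- intercept + slope * x0
  if (is.na(baseline) || baseline <= 0) {
    warning("nonpositive fitted baseline expression; delta_e undefined")
    de <- NA_real_
  } else {
    de <- slope / baseline
  }
  structure(list(gene = if (is.null(gene)) NA_character_ else gene,
                 predictor = predictor, slope = slope, intercept = intercept,
                 baseline_count = x0, baseline = baseline,
                 pearson_r = r, p_value = p, delta_e = de, n = length(x)),
            class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat(sprintf("dosage fit: %s ~ %s  (n = %d)\n",
              ifelse(is.na(x$gene), "expression", x$gene), x$predictor, x$n))
  cat(sprintf("  slope %.4g TPM/copy, baseline %.4g TPM at %s = %d\n",
              x$slope, x$baseline, x$predictor, x$baseline_count))
  cat(sprintf("  delta_e %.4g, Pearson r %.3f, p %.3g\n",
              x$delta_e, x$pearson_r, x$p_value))
  invisible(x)
}

#' Fractional expression change per added chromosome
#'
#' Extracts `delta_e` — the regression slope divided by the fitted
#' expression at the single-copy baseline — from a [fit_dosage_response()]
#' object, or computes it from an explicit slope and baseline.
#'
#' @param fit a `"dosage_fit"`, or a numeric slope when `baseline` is given.
#' @param baseline fitted expression at the baseline copy number (`> 0`).
#' @return The dimensionless fractional increment per added chromosome.
#' @examples
#' delta_e(26, baseline = 100)  # 0.26
#' @export
delta_e <- function(fit, baseline = NULL) {
  if (inherits(fit, "dosage_fit")) return(fit$delta_e)
  if (is.null(baseline))
    stop("supply a dosage_fit or both slope and baseline", call. = FALSE)
  if (!is.numeric(fit) || !is.numeric(baseline))
    stop("slope and baseline must be numeric", call. = FALSE)
  out <- fit / baseline
  bad <- !is.na(baseline) & baseline <= 0
  if (any(bad)) {
    warning("nonpositive baseline; delta_e undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Dosage-response fits for several genes
#'
#' @param metadata,tpm,predictor as in [fit_dosage_response()].
#' @param genes character vector of gene ids (default: all rows of `tpm`).
#' @return data.frame with one row per gene (slope, baseline, pearson_r,
#'   p_value, delta_e, n).
#' @export
dosage_fit_table <- function(metadata, tpm, genes = rownames(tpm),
                             predictor = c("nX", "nY", "n21")) {
  predictor <- match.arg(predictor)
  rows <- lapply(genes, function(g) {
    f <- fit_dosage_response(metadata, tpm, g, predictor)
    data.frame(gene = g, predictor = predictor, slope = f$slope,
               intercept = f$intercept, baseline = f$baseline,
               pearson_r = f$pearson_r, p_value = f$p_value,
               delta_e = f$delta_e, n = f$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allelic ratio of Xi- to Xa-derived transcripts
#'
#' Reads are summed across informative sites upstream; this is the simple
#' ratio of the summed counts. A sample with no Xa reads has an undefined
#' ratio and returns `NA` with a warning.
#'
#' @param xi_reads,xa_reads nonnegative counts (vectorized).
#' @return `xi_reads / xa_reads`.
#' @examples
#' allelic_ratio(55, 100)  # 0.55
#' @export
allelic_ratio <- function(xi_reads, xa_reads) {
  if (!is.numeric(xi_reads) || !is.numeric(xa_reads) ||
      any(xi_reads < 0, na.rm = TRUE) || any(xa_reads < 0, na.rm = TRUE))
    stop("read counts must be nonnegative", call. = FALSE)
  out <- xi_reads / xa_reads
  if (any(xa_reads == 0, na.rm = TRUE)) {
    warning("xa_reads = 0; allelic ratio undefined for those samples")
    out[xa_reads == 0] <- NA_real_
  }
  out
}

#' Compare per-sample allelic ratios with a gene's delta_e
#'
#' One-sample t-test of the allelic-ratio observations against the null that
#' their mean equals the gene's fractional dosage response `delta_e`. If
#' expression from Xi and Xa were independent and additive the two
#' quantities would agree; a significantly higher AR than delta_e indicates
#' that added copies contribute less than their allelic share, i.e.
#' negative regulation. `delta_e` is treated as a known constant.
#'
#' @param ar_values numeric vector of per-sample allelic ratios (`>= 3`).
#' @param delta_e the gene's fractional increment per added X.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `statistic`, `df`, `p_value`, `mean_ar`, `delta_e`,
#'   `alternative`.
#' @export
compare_ar_delta_e <- function(ar_values, delta_e,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ar_values <- ar_values[is.finite(ar_values)]
  if (length(ar_values) < 3L)
    stop("need at least 3 allelic-ratio observations", call. = FALSE)
  .check_scalar(delta_e, "delta_e")
  if (stats::sd(ar_values) == 0) {
    warning("zero variance in allelic ratios; exact decision reported")
    p <- if (isTRUE(all.equal(mean(ar_values), delta_e))) 1 else 0
    return(list(statistic = NA_real_, df = length(ar_values) - 1L,
                p_value = p, mean_ar = mean(ar_values), delta_e = delta_e,
                alternative = alternative))
  }
  tt <- stats::t.test(ar_values, mu = delta_e, alternative = alternative)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_ar = mean(ar_values), delta_e = delta_e,
       alternative = alternative)
}

#' Select XY cell lines by marker-gene expression
#'
#' Retains lines with clear Y-linked expression and no X-inactivation
#' signature: `log2TPM(DDX3Y) > 0.2`, `log2TPM(RPS4Y1) > 0.2` and
#' `log2TPM(XIST) < 2`, all strict. Lines with a missing marker value are
#' excluded with a warning.
#'
#' @param log2tpm data.frame or matrix with one row per line and columns
#'   (case-insensitive) `DDX3Y`, `RPS4Y1`, `XIST`.
#' @return Named logical vector: `TRUE` for retained lines.
#' @examples
#' classify_xy_lines(data.frame(DDX3Y = c(1, 1), RPS4Y1 = c(1, 1),
#'                              XIST = c(0.5, 3)))
#' @export
classify_xy_lines <- function(log2tpm) {
  m <- as.data.frame(log2tpm)
  idx <- match(c("ddx3y", "rps4y1", "xist"), tolower(names(m)))
  if (any(is.na(idx)))
    stop("log2tpm must contain columns DDX3Y, RPS4Y1, XIST", call. = FALSE)
  ddx3y <- as.numeric(m[[idx[1]]])
  rps4y1 <- as.numeric(m[[idx[2]]])
  xist <- as.numeric(m[[idx[3]]])
  keep <- ddx3y > 0.2 & rps4y1 > 0.2 & xist < 2
  missing <- is.na(ddx3y) | is.na(rps4y1) | is.na(xist)
  if (any(missing)) {
    warning(sum(missing), " line(s) with missing marker values excluded")
    keep[missing] <- FALSE
  }
  names(keep) <- rownames(m)
  keep
}
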