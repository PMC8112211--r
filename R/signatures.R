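#' Disease expression signature from a case/control cohort
#'
#' Tests every gene for differential expression between case and control
#' samples with a two-sided Welch t-test on log2(x + 1)-transformed values,
#' adjusts p-values by Benjamini-Hochberg, and calls a gene active when
#' |log2FC| strictly exceeds `lfc_threshold` AND the adjusted p-value is
#' strictly below `fdr_threshold`. log2FC is the difference of condition
#' means on the transformed scale (case minus control). Both inequalities are
#' strict, so a gene sitting exactly on either threshold is excluded.
#'
#' Genes that are constant across all samples carry no information for the
#' Welch test and are excluded with a warning.
#'
#' @param cohort an [expression_cohort()]; needs >= 2 samples per condition
#'   and non-negative expression values.
#' @param lfc_threshold positive log2 fold-change cutoff (default 1).
#' @param fdr_threshold BH-adjusted p-value cutoff in (0, 1] (default 0.1).
#' @return A [signed_signature()] over the tested genes with
#'   `magnitude` = log2FC and `support` = 1 for active genes, plus attributes
#'   `stats` (per-gene data.frame: log2fc, p, padj) and `n_up` / `n_down`.
#' @export
compute_disease_signature <- function(cohort, lfc_threshold = 1,
                                      fdr_threshold = 0.1) {
  stopifnot(inherits(cohort, "expression_cohort"),
            lfc_threshold > 0, fdr_threshold > 0, fdr_threshold <= 1)
  for (lab in c("case", "control")) {
    if (!any(cohort$condition == lab)) {
      stop(sprintf("condition '%s' has no samples", lab))
    }
  }
  is_case <- cohort$condition == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("need at least 2 samples per condition")
  }
  if (any(cohort$values < 0)) stop("expression values must be non-negative")

  x <- log2(cohort$values + 1)
  constant <- apply(x, 1L, function(r) max(r) == min(r))
  if (any(constant)) {
    warning(sprintf("%d constant gene row(s) excluded from testing",
                    sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no non-constant genes to test")

  welch <- row_welch(x[, is_case, drop = FALSE], x[, !is_case, drop = FALSE])
  padj <- stats::p.adjust(welch$p, method = "BH")
  lfc <- welch$delta
  active <- abs(lfc) > lfc_threshold & padj < fdr_threshold
  active[is.na(active)] <- FALSE

  dir <- ifelse(active, sign(lfc), 0L)
  sig <- signed_signature(rownames(x), dir,
                          magnitude = ifelse(active, lfc, 0),
                          support = as.integer(active))
  attr(sig, "stats") <- data.frame(gene = rownames(x), log2fc = lfc,
                                   p = welch$p, padj = padj,
                                   stringsAsFactors = FALSE, row.names = NULL)
  attr(sig, "n_up") <- sum(dir > 0)
  attr(sig, "n_down") <- sum(dir < 0)
  sig
}

# Vectorized two-sided Welch t-test over matrix rows (groups in columns).
# Returns per-row mean difference (a - b) and p-value. Rows where both groups
# have zero variance get p = NA (no test possible).
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- NA_real_
  list(delta = ma - mb, p = p)
}

#' Transcriptional consensus signature (TCS) of a compound
#'
#' Aggregates a compound's perturbation profiles into a per-gene consensus
#' across cell lines. Within each cell line the gene's call is the sign of
#' the median differential score over that cell line's experiments, zeroed
#' when |median| < `per_experiment_threshold`. The TCS direction is the
#' majority sign when a strict majority of the calling (non-zero) cell lines
#' agree, and 0 on an exact tie; support counts the cell lines sharing the
#' majority sign, so the maximum attainable support equals the number of
#' cell lines in the panel.
#'
#' @param panel a [perturbation_panel()].
#' @param compound compound ID present in the panel.
#' @param per_experiment_threshold non-negative absolute-median cutoff below
#'   which a cell line abstains for that gene (default 0: pure sign of the
#'   median).
#' @return A [signed_signature()] with `support` = number of agreeing cell
#'   lines and `magnitude` = mean of the agreeing cell-line medians.
#' @export
compute_tcs <- function(panel, compound, per_experiment_threshold = 0) {
  stopifnot(inherits(panel, "perturbation_panel"),
            per_experiment_threshold >= 0)
  keep <- panel$records$compound == compound
  if (!any(keep)) stop(sprintf("compound '%s' not in panel", compound))
  scores <- panel$scores[, keep, drop = FALSE]
  cls <- panel$records$cell_line[keep]

  # genes x cell-lines matrix of per-cell-line median scores
  meds <- vapply(unique(cls), function(cl) {
    m <- scores[, cls == cl, drop = FALSE]
    apply(m, 1L, stats::median)
  }, numeric(nrow(scores)))
  if (is.null(dim(meds))) {
    # single-gene universe: vapply collapsed the genes dimension
    meds <- matrix(meds, nrow = nrow(scores))
  }

  calls <- sign(meds)
  calls[abs(meds) < per_experiment_threshold] <- 0

  n_pos <- rowSums(calls > 0)
  n_neg <- rowSums(calls < 0)
  dir <- ifelse(n_pos > n_neg, 1L, ifelse(n_neg > n_pos, -1L, 0L))
  support <- ifelse(dir > 0L, n_pos, ifelse(dir < 0L, n_neg, 0L))

  agree <- sweep(calls, 1L, dir, `==`) & dir != 0L
  mag_sum <- rowSums(meds * agree)
  magnitude <- ifelse(support > 0L, mag_sum / pmax(support, 1L), 0)

  signed_signature(rownames(scores), dir, magnitude, as.integer(support))
}

#' Robust reference signature of an approved disease drug
#'
#' Builds a reference signature from a compound's individual experiments in
#' a chosen cell-line context: a gene is active when the same sign occurs in
#' at least `min_fraction` of the filtered experiments (and strictly more
#' often than the opposite sign; an exact tie deactivates the gene). Support
#' counts the agreeing experiments. This mirrors requiring consistent
#' transcriptional changes in at least half of the contexts to obtain a
#' robust signature.
#'
#' @param panel a [perturbation_panel()].
#' @param compound compound ID.
#' @param cell_line_filter cell-line IDs to restrict to (default: all cell
#'   lines carrying the compound).
#' @param min_fraction required fraction of agreeing experiments (default 0.5).
#' @return A [signed_signature()] with `magnitude` = mean score over the
#'   agreeing experiments.
#' @export
compute_reference_signature <- function(panel, compound,
                                        cell_line_filter = NULL,
                                        min_fraction = 0.5) {
  stopifnot(inherits(panel, "perturbation_panel"),
            min_fraction > 0, min_fraction <= 1)
  keep <- panel$records$compound == compound
  if (!any(keep)) stop(sprintf("compound '%s' not in panel", compound))
  if (!is.null(cell_line_filter)) {
    keep <- keep & panel$records$cell_line %in% cell_line_filter
    if (!any(keep)) {
      stop("no experiments left after applying the cell-line filter")
    }
  }
  scores <- panel$scores[, keep, drop = FALSE]
  n_exp <- ncol(scores)

  n_pos <- rowSums(scores > 0)
  n_neg <- rowSums(scores < 0)
  pos_ok <- n_pos / n_exp >= min_fraction
  neg_ok <- n_neg / n_exp >= min_fraction
  dir <- integer(nrow(scores))
  dir[pos_ok & n_pos > n_neg] <- 1L
  dir[neg_ok & n_neg > n_pos] <- -1L

  support <- ifelse(dir > 0L, n_pos, ifelse(dir < 0L, n_neg, 0L))
  mag <- numeric(nrow(scores))
  up <- dir == 1L
  dn <- dir == -1L
  pos_mean <- rowSums(scores * (scores > 0)) / pmax(n_pos, 1L)
  neg_mean <- rowSums(scores * (scores < 0)) / pmax(n_neg, 1L)
  mag[up] <- pos_mean[up]
  mag[dn] <- neg_mean[dn]

  signed_signature(rownames(scores), dir, mag, as.integer(support))
}
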