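#' Signed gene signature
#'
#' A signed signature records, for every gene in its universe, a direction in
#' \{-1, 0, +1\}, a signed effect-size magnitude, and a non-negative integer
#' support (consensus count). Direction 0 means the gene belongs to the
#' universe but is not part of the active signature; such genes carry
#' magnitude 0 and support 0. The same container holds the disease signature,
#' a compound's transcriptional consensus signature (TCS), and a reference
#' drug's robust signature.
#'
#' @param gene character vector of gene identifiers (no duplicates).
#' @param direction integer vector in \{-1, 0, 1\}, one per gene.
#' @param magnitude numeric effect sizes; sign must agree with `direction`
#'   wherever `direction != 0`.
#' @param support non-negative integer consensus counts; 0 where inactive.
#'
#' @return A `signed_signature`: a data.frame with columns `gene`,
#'   `direction`, `magnitude`, `support`.
#' @export
signed_signature <- function(gene, direction,
                             magnitude = as.numeric(direction),
                             support = as.integer(direction != 0)) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene identifiers in signature")
  direction <- as.integer(direction)
  if (!all(direction %in% c(-1L, 0L, 1L))) {
    stop("direction must be -1, 0 or +1")
  }
  magnitude <- as.numeric(magnitude)
  support <- as.integer(support)
  if (any(support < 0L)) stop("support must be non-negative")
  active <- direction != 0L
  if (any(active & sign(magnitude) != direction)) {
    stop("magnitude sign disagrees with direction for an active gene")
  }
  magnitude[!active] <- 0
  support[!active] <- 0L
  out <- data.frame(gene = gene, direction = direction,
                    magnitude = magnitude, support = support,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("signed_signature", "data.frame")
  out
}

#' @export
print.signed_signature <- function(x, ...) {
  n_up <- sum(x$direction > 0L)
  n_dn <- sum(x$direction < 0L)
  cat(sprintf("Signed signature: %d genes in universe, %d active (%d up, %d down)\n",
              nrow(x), n_up + n_dn, n_up, n_dn))
  invisible(x)
}

#' Number of active genes in a signature
#' @param x a `signed_signature`.
#' @return integer count of genes with non-zero direction.
#' @export
n_active <- function(x) {
  stopifnot(inherits(x, "signed_signature"))
  sum(x$direction != 0L)
}

# Named direction vector keyed by gene, for set algebra between signatures.
signature_dirs <- function(x) {
  stats::setNames(x$direction, x$gene)
}

#' Case/control expression cohort
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Counts or normalized non-negative
#'   units; stated in `units`.
#' @param condition character vector over samples, each "case" or "control".
#' @param units free-text description of the value scale (e.g. "counts").
#'
#' @return An `expression_cohort` list with elements `values`, `condition`,
#'   `units`.
#' @export
expression_cohort <- function(values, condition, units = "counts") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs in cohort")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("one condition label per sample is required")
  }
  if (!all(condition %in% c("case", "control"))) {
    stop("condition labels must be 'case' or 'control'")
  }
  structure(list(values = values, condition = condition, units = units),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort: %d genes x %d samples (%d case / %d control), units: %s\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control"),
              x$units))
  invisible(x)
}

#' Drug-perturbation profile panel
#'
#' Holds per-experiment signed differential-expression scores for a library
#' of compounds across cell lines, mirroring an L1000 Level-4 style layout:
#' one score column per (compound, cell line, experiment) record over a
#' shared gene universe.
#'
#' @param scores numeric matrix, genes x records; rownames are gene IDs.
#' @param records data.frame with one row per score column and columns
#'   `compound`, `cell_line`, `experiment`.
#'
#' @return A `perturbation_panel` list with elements `scores`, `records`.
#' @export
perturbation_panel <- function(scores, records) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) stop("score matrix needs gene rownames")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("compound", "cell_line", "experiment")
  if (!all(need %in% names(records))) {
    stop("records must have columns compound, cell_line, experiment")
  }
  if (nrow(records) != ncol(scores)) {
    stop("one record row per score column is required")
  }
  if (any(!is.finite(scores))) stop("perturbation scores must be finite")
  if (any(!nzchar(records$compound)) || any(!nzchar(records$cell_line))) {
    stop("compound and cell-line IDs must be non-empty")
  }
  structure(list(scores = scores, records = records),
            class = "perturbation_panel")
}

#' @export
print.perturbation_panel <- function(x, ...) {
  cat(sprintf("Perturbation panel: %d genes, %d records (%d compounds, %d cell lines)\n",
              nrow(x$scores), nrow(x$records),
              length(unique(x$records$compound)),
              length(unique(x$records$cell_line))))
  invisible(x)
}

#' Protein set (drug targets or disease proteins)
#'
#' @param label set label, e.g. a drug name or "disease".
#' @param members character vector of protein IDs.
#' @return A `protein_set` list with `label` and the deduplicated `members`.
#' @export
protein_set <- function(label, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop(sprintf("protein set '%s' is empty", label))
  structure(list(label = as.character(label), members = members),
            class = "protein_set")
}
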