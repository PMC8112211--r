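# Readers and writers for the plain-text formats the pipeline consumes:
# expression TSV (genes x samples) + condition TSV, perturbation-panel TSV,
# signature TSV, edge-list TSV, protein-set TSV, dose-matrix CSV.

#' Read an expression cohort from TSV
#'
#' Expression file: first column gene ID, remaining columns one per sample,
#' header row sample IDs. Condition file: two columns `sample`, `condition`
#' ("case"/"control").
#'
#' @param expression_file path to the genes-x-samples TSV.
#' @param condition_file path to the sample-to-condition TSV.
#' @param units value scale recorded in the cohort metadata.
#' @return An [expression_cohort()].
#' @export
read_expression_tsv <- function(expression_file, condition_file,
                                units = "counts") {
  tab <- utils::read.delim(expression_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  cond <- utils::read.delim(condition_file, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(cond))) {
    stop("condition file must have columns 'sample' and 'condition'")
  }
  idx <- match(colnames(mat), cond$sample)
  if (anyNA(idx)) {
    stop("samples without a condition label: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  }
  expression_cohort(mat, cond$condition[idx], units = units)
}

#' Write / read a signed signature as TSV
#'
#' Columns: gene, direction, magnitude, support.
#'
#' @param x a [signed_signature()].
#' @param file output path.
#' @return `write_signature_tsv` returns `file` invisibly;
#'   `read_signature_tsv` returns a `signed_signature`.
#' @export
write_signature_tsv <- function(x, file) {
  stopifnot(inherits(x, "signed_signature"))
  utils::write.table(as.data.frame(x), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character"))
  signed_signature(tab$gene, tab$direction, tab$magnitude, tab$support)
}

#' Read / write a perturbation panel as long-format TSV
#'
#' Long format with columns compound, cell_line, experiment, gene, score;
#' reshaped internally to a genes-x-records score matrix.
#'
#' @param file path to the TSV.
#' @return A [perturbation_panel()].
#' @export
read_panel_tsv <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(gene = "character"))
  need <- c("compound", "cell_line", "experiment", "gene", "score")
  if (!all(need %in% names(tab))) {
    stop("panel TSV must have columns ", paste(need, collapse = ", "))
  }
  rec_key <- paste(tab$compound, tab$cell_line, tab$experiment, sep = "\r")
  keys <- unique(rec_key)
  genes <- unique(tab$gene)
  mat <- matrix(0, nrow = length(genes), ncol = length(keys),
                dimnames = list(genes, NULL))
  mat[cbind(match(tab$gene, genes), match(rec_key, keys))] <- tab$score
  parts <- strsplit(keys, "\r", fixed = TRUE)
  records <- data.frame(compound = vapply(parts, `[`, "", 1L),
                        cell_line = vapply(parts, `[`, "", 2L),
                        experiment = vapply(parts, `[`, "", 3L),
                        stringsAsFactors = FALSE)
  perturbation_panel(mat, records)
}

#' @rdname read_panel_tsv
#' @param panel a [perturbation_panel()] to serialize.
#' @export
write_panel_tsv <- function(panel, file) {
  stopifnot(inherits(panel, "perturbation_panel"))
  long <- data.frame(
    compound = rep(panel$records$compound, each = nrow(panel$scores)),
    cell_line = rep(panel$records$cell_line, each = nrow(panel$scores)),
    experiment = rep(panel$records$experiment, each = nrow(panel$scores)),
    gene = rep(rownames(panel$scores), times = ncol(panel$scores)),
    score = as.vector(panel$scores),
    stringsAsFactors = FALSE)
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV (optionally with header `from`/`to`) or SIF
#' (`a interaction b`). Self-loops and duplicate edges are dropped so the
#' result is a simple undirected graph.
#'
#' @param file path to the edge list.
#' @param format "tsv" or "sif".
#' @return An [igraph::graph] (undirected, simple).
#' @export
read_edgelist <- function(file, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    tab <- utils::read.table(file, stringsAsFactors = FALSE)
    edges <- cbind(tab[[1L]], tab[[3L]])
  } else {
    first <- utils::read.delim(file, nrows = 1L, header = FALSE,
                               stringsAsFactors = FALSE)
    has_header <- identical(tolower(as.character(first[1, 1:2])),
                            c("from", "to"))
    tab <- utils::read.delim(file, header = has_header,
                             stringsAsFactors = FALSE)
    edges <- cbind(as.character(tab[[1L]]), as.character(tab[[2L]]))
  }
  ppi_graph(edges)
}

#' Read protein sets from TSV
#'
#' Two columns `label`, `protein`; returns one [protein_set()] per label.
#'
#' @param file path to the TSV.
#' @return Named list of `protein_set` objects.
#' @export
read_protein_sets <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("label", "protein") %in% names(tab))) {
    stop("protein-set TSV must have columns 'label' and 'protein'")
  }
  sets <- split(tab$protein, tab$label)
  lapply_named <- lapply(names(sets), function(l) protein_set(l, sets[[l]]))
  stats::setNames(lapply_named, names(sets))
}

#' Read a dose-response checkerboard CSV
#'
#' Layout: first cell ignored/label, first row = doses of drug B, first
#' column = doses of drug A, body = response. `scale = "viability"` converts
#' percent viability to inhibition fractions via `1 - v / v_control`, where
#' the control is the (0, 0) well.
#'
#' @param file path to the CSV.
#' @param scale "inhibition" (fractions in [0, 1]) or "viability"
#'   (plate-reader percent or relative viability).
#' @param drug_a,drug_b drug names recorded in the result.
#' @return A [dose_response_matrix()].
#' @export
read_dose_matrix_csv <- function(file, scale = c("inhibition", "viability"),
                                 drug_a = "drugA", drug_b = "drugB") {
  scale <- match.arg(scale)
  tab <- utils::read.csv(file, check.names = FALSE, row.names = 1L)
  mat <- as.matrix(tab)
  doses_a <- as.numeric(rownames(tab))
  doses_b <- as.numeric(colnames(tab))
  if (scale == "viability") {
    v0 <- mat[1L, 1L]
    if (!is.finite(v0) || v0 <= 0) stop("control (0,0) viability must be positive")
    mat <- 1 - mat / v0
  }
  dose_response_matrix(mat, doses_a, doses_b,
                       drug_a = drug_a, drug_b = drug_b)
}

#' @rdname read_dose_matrix_csv
#' @param x a [dose_response_matrix()] to serialize (inhibition scale).
#' @export
write_dose_matrix_csv <- function(x, file) {
  stopifnot(inherits(x, "dose_response_matrix"))
  out <- x$response
  rownames(out) <- x$doses_a
  colnames(out) <- x$doses_b
  utils::write.csv(out, file, quote = FALSE)
  invisible(file)
}
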