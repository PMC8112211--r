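# Transcriptional orthogonality of a candidate compound to a reference drug:
# concordance ratio (CR) on genes active in both signatures, disease
# discordance ratio (DR) on disease genes missing from the reference, and the
# combined orthogonality score OS = sqrt((1 - CR)^2 + DR^2). High OS marks a
# compound whose transcriptional impact is complementary to the reference
# while reversing the disease signature.

# Align two (or three) signatures on the intersection of their gene
# universes and return the direction vectors.
align_dirs <- function(...) {
  sigs <- list(...)
  universes <- lapply(sigs, function(s) s$gene)
  common <- Reduce(intersect, universes)
  if (length(common) == 0L) stop("signature gene universes do not intersect")
  lapply(sigs, function(s) s$direction[match(common, s$gene)])
}

#' Concordance ratio between a compound and a reference signature
#'
#' Over genes active in both the compound TCS `z` and the reference
#' signature `r` (restricted to their shared gene universe), counts genes
#' with matching sign (`n_same`, sign product > 0) and opposite sign
#' (`n_opp`, product < 0). Genes inactive in either signature contribute to
#' neither count.
#'
#' Two conventions are supported: `"normalized"` returns the fraction
#' `n_same / (n_same + n_opp)` (bounded in [0, 1], the default used for
#' ranking); `"as_printed"` returns the literal same:opposite ratio
#' `n_same / n_opp`, which is unbounded and becomes an `Inf` sentinel with
#' `flagged = TRUE` when `n_opp = 0`. When no gene is active in both
#' signatures the ratio is undefined (`NA`, flagged).
#'
#' @param z compound [signed_signature()].
#' @param r reference [signed_signature()] with >= 1 active gene.
#' @param mode "normalized" or "as_printed".
#' @return List with `cr`, `n_same`, `n_opp`, `flagged`.
#' @export
concordance_ratio <- function(z, r, mode = c("normalized", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(z, "signed_signature"), inherits(r, "signed_signature"))
  if (n_active(r) == 0L) stop("reference signature has no active genes")
  d <- align_dirs(z, r)
  prod <- d[[1L]] * d[[2L]]
  n_same <- sum(prod > 0L)
  n_opp <- sum(prod < 0L)
  ratio_pair(n_same, n_opp, mode, value_name = "cr",
             counts = list(n_same = n_same, n_opp = n_opp))
}

#' Disease discordance ratio
#'
#' Restricts to disease-signature genes missing from the reference signature
#' (reference direction 0 on the shared universe of `z`, `d` and `r`) where
#' both the compound and the disease call a direction, and counts compound
#' calls that reverse the disease (`n_disc`, sign product z*d < 0) versus
#' mimic it (`n_conc`, product > 0). `"normalized"` returns
#' `n_disc / (n_disc + n_conc)`; `"as_printed"` the literal ratio
#' `n_disc / n_conc`. An empty eligible set gives an undefined, flagged
#' ratio.
#'
#' @param z compound [signed_signature()].
#' @param d disease [signed_signature()] with >= 1 active gene.
#' @param r reference [signed_signature()].
#' @inheritParams concordance_ratio
#' @return List with `dr`, `n_disc`, `n_conc`, `flagged`.
#' @export
discordance_ratio <- function(z, d, r, mode = c("normalized", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(z, "signed_signature"),
            inherits(d, "signed_signature"),
            inherits(r, "signed_signature"))
  if (n_active(d) == 0L) stop("disease signature has no active genes")
  a <- align_dirs(z, d, r)
  eligible <- a[[3L]] == 0L
  prod <- a[[1L]][eligible] * a[[2L]][eligible]
  n_disc <- sum(prod < 0L)
  n_conc <- sum(prod > 0L)
  ratio_pair(n_disc, n_conc, mode, value_name = "dr",
             counts = list(n_disc = n_disc, n_conc = n_conc))
}

ratio_pair <- function(num, den, mode, value_name, counts) {
  if (num + den == 0L) {
    val <- NA_real_; flagged <- TRUE
  } else if (mode == "normalized") {
    val <- num / (num + den); flagged <- FALSE
  } else if (den == 0L) {
    val <- Inf; flagged <- TRUE
  } else {
    val <- num / den; flagged <- FALSE
  }
  c(stats::setNames(list(val), value_name), counts, list(flagged = flagged))
}

#' Orthogonality score
#'
#' `OS = sqrt((1 - CR)^2 + DR^2)`. With normalized CR and DR in [0, 1], OS
#' ranges from 0 (transcriptional twin of the reference that never reverses
#' the disease) to sqrt(2) (fully complementary to the reference and fully
#' disease-reversing).
#'
#' @param cr,dr finite concordance and discordance ratios.
#' @return The orthogonality score (non-negative numeric).
#' @export
orthogonality_score <- function(cr, dr) {
  if (!all(is.finite(cr)) || !all(is.finite(dr))) {
    stop("CR and DR must be finite to compute an orthogonality score")
  }
  sqrt((1 - cr)^2 + dr^2)
}

#' Rank library compounds by orthogonality to a reference drug
#'
#' Builds the reference signature and every other compound's TCS from the
#' panel, scores each compound's CR (vs the reference), DR (vs the disease
#' signature on genes the reference misses) and OS, and ranks by OS
#' descending. Ties break by higher DR, then lexicographic compound ID, so
#' reruns are bit-identical. Compounds with undefined CR or DR are excluded
#' from the ranking and reported separately.
#'
#' @param panel a [perturbation_panel()] holding the compound library.
#' @param reference reference compound ID (scored against the others, not
#'   ranked itself).
#' @param disease disease [signed_signature()].
#' @param top_k number of top candidates to return (default 3).
#' @param mode ratio convention, see [concordance_ratio()].
#' @param reference_signature optional precomputed reference
#'   [signed_signature()]; by default [compute_reference_signature()] over
#'   all of the reference's panel experiments.
#' @param per_experiment_threshold passed to [compute_tcs()].
#' @return An `orthogonality_ranking` list: `table` (all valid records,
#'   ranked), `top` (first `top_k` rows), `flagged` (excluded compounds),
#'   `reference`.
#' @export
rank_candidates <- function(panel, reference, disease, top_k = 3L,
                            mode = c("normalized", "as_printed"),
                            reference_signature = NULL,
                            per_experiment_threshold = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "perturbation_panel"),
            inherits(disease, "signed_signature"))
  r <- reference_signature
  if (is.null(r)) r <- compute_reference_signature(panel, reference)
  if (n_active(r) == 0L) stop("reference signature has no active genes")

  compounds <- setdiff(sort(unique(panel$records$compound)), reference)
  rows <- lapply(compounds, function(cp) {
    z <- compute_tcs(panel, cp, per_experiment_threshold)
    cr <- concordance_ratio(z, r, mode)
    dr <- discordance_ratio(z, disease, r, mode)
    flagged <- cr$flagged || dr$flagged
    os <- if (flagged) NA_real_ else orthogonality_score(cr$cr, dr$dr)
    data.frame(compound = cp, cr = cr$cr, dr = dr$dr, os = os,
               n_same = cr$n_same, n_opp = cr$n_opp,
               n_disc = dr$n_disc, n_conc = dr$n_conc,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  flagged_tab <- tab[tab$flagged, , drop = FALSE]
  valid <- tab[!tab$flagged, , drop = FALSE]
  ord <- order(-valid$os, -valid$dr, valid$compound, method = "radix")
  valid <- valid[ord, , drop = FALSE]
  rownames(valid) <- NULL
  if (top_k > nrow(valid)) {
    warning(sprintf("top_k = %d exceeds the %d valid records; returning all",
                    top_k, nrow(valid)))
    top_k <- nrow(valid)
  }
  structure(list(table = valid, top = valid[seq_len(top_k), , drop = FALSE],
                 flagged = flagged_tab, reference = reference, mode = mode),
            class = "orthogonality_ranking")
}

#' @export
print.orthogonality_ranking <- function(x, ...) {
  cat(sprintf("Orthogonality ranking vs reference '%s' (%s mode): %d valid, %d flagged\n",
              x$reference, x$mode, nrow(x$table), nrow(x$flagged)))
  cat("Top candidates:\n")
  print(x$top[, c("compound", "cr", "dr", "os")], digits = 4)
  invisible(x)
}

#' Write a ranking table to TSV
#' @param x an `orthogonality_ranking`.
#' @param file output path.
#' @export
write_ranking_tsv <- function(x, file) {
  stopifnot(inherits(x, "orthogonality_ranking"))
  out <- rbind(x$table, x$flagged)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Correlation network and clustering of compound consensus signatures
#'
#' Computes pairwise Pearson correlation between compound TCS vectors
#' (direction x support per gene, on the shared universe), keeps edges with
#' r strictly above `threshold`, and clusters compounds by average-linkage
#' hierarchical clustering on distance 1 - r, cutting the tree at height
#' `1 - threshold`. Compounds whose signature vector has zero variance have
#' no defined correlation and are excluded with a warning.
#'
#' @param tcs_set named list of [signed_signature()] objects (>= 2).
#' @param threshold correlation cutoff for edges (default 0.7).
#' @param linkage hierarchical-clustering linkage; only "average" is offered.
#' @param use_raw_direction if TRUE correlate plain directions instead of
#'   direction x support.
#' @return A `correlation_network` list: `nodes`, `edges` (data.frame i, j,
#'   r), `clusters` (named integer vector), `correlation` matrix,
#'   `excluded`.
#' @export
tcs_correlation_network <- function(tcs_set, threshold = 0.7,
                                    linkage = "average",
                                    use_raw_direction = FALSE) {
  linkage <- match.arg(linkage, "average")
  stopifnot(length(tcs_set) >= 2L)
  if (is.null(names(tcs_set))) {
    names(tcs_set) <- paste0("compound", seq_along(tcs_set))
  }
  common <- Reduce(intersect, lapply(tcs_set, function(s) s$gene))
  if (length(common) < 2L) stop("shared gene universe too small to correlate")
  vecs <- vapply(tcs_set, function(s) {
    i <- match(common, s$gene)
    if (use_raw_direction) as.numeric(s$direction[i])
    else as.numeric(s$direction[i]) * s$support[i]
  }, numeric(length(common)))

  sds <- apply(vecs, 2L, stats::sd)
  excluded <- colnames(vecs)[sds == 0]
  if (length(excluded) > 0L) {
    warning("zero-variance signature(s) excluded: ",
            paste(excluded, collapse = ", "))
    vecs <- vecs[, sds > 0, drop = FALSE]
  }
  if (ncol(vecs) < 2L) stop("fewer than 2 usable signatures after exclusion")

  cm <- stats::cor(vecs)
  nodes <- colnames(cm)
  idx <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  edges <- data.frame(i = nodes[idx[, 1L]], j = nodes[idx[, 2L]],
                      r = cm[idx], stringsAsFactors = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  clusters <- stats::cutree(hc, h = 1 - threshold)
  structure(list(nodes = nodes, edges = edges, clusters = clusters,
                 correlation = cm, excluded = excluded,
                 threshold = threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("TCS correlation network: %d compounds, %d edges (r > %.2f), %d clusters\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              length(unique(x$clusters))))
  invisible(x)
}
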