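# Network pharmacology on a protein-protein interaction (PPI) graph:
# closest-distance proximity of drug targets to disease proteins, a
# degree-matched permutation null giving a z-score, the separation score
# s_AB between two drugs' target modules, and the resulting exposure
# classification of a drug pair relative to the disease module.

#' Build a simple undirected PPI graph
#'
#' @param edges two-column character matrix or data.frame of interacting
#'   protein pairs. Self-loops and duplicate edges are removed.
#' @return An undirected simple [igraph::graph].
#' @export
ppi_graph <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edge list must have two columns")
  mode(edges) <- "character"
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

set_members <- function(s) {
  if (inherits(s, "protein_set")) s$members else unique(as.character(s))
}

# Restrict a protein set to the graph's largest connected component,
# warning about dropped members.
lcc_filter <- function(graph, members, label) {
  comp <- igraph::components(graph)
  lcc <- igraph::V(graph)$name[comp$membership == which.max(comp$csize)]
  keep <- intersect(members, lcc)
  dropped <- setdiff(members, keep)
  if (length(dropped) > 0L) {
    warning(sprintf("%d member(s) of '%s' outside the largest connected component dropped: %s",
                    length(dropped), label,
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  }
  if (length(keep) == 0L) {
    stop(sprintf("protein set '%s' is empty after graph filtering", label))
  }
  keep
}

#' Closest network distance from drug targets to disease proteins
#'
#' `d(X, Y) = (1/|Y|) * sum over y in Y of min over x in X of d(x, y)` with
#' unweighted shortest-path (hop-count) distances. Members of either set
#' outside the graph's largest connected component are dropped with a
#' warning. The measure is directional: Y is averaged over, X is minimized
#' over, so `closest_distance(g, X, Y)` need not equal
#' `closest_distance(g, Y, X)`.
#'
#' @param graph PPI graph (igraph, undirected).
#' @param X drug-target [protein_set()] (or character vector).
#' @param Y disease-protein [protein_set()] (or character vector).
#' @return The mean closest distance (non-negative numeric).
#' @export
closest_distance <- function(graph, X, Y) {
  xs <- lcc_filter(graph, set_members(X), "X")
  ys <- lcc_filter(graph, set_members(Y), "Y")
  mean_closest(graph, xs, ys)
}

# Filtering-free core of closest_distance (callers guarantee membership).
mean_closest <- function(graph, xs, ys) {
  dm <- igraph::distances(graph, v = ys, to = xs)
  mean(apply(dm, 1L, min))
}

# Degree-matched candidate pools: log2 degree bins, widened symmetrically
# until each pool holds at least `min_bin` candidates.
degree_pools <- function(graph, nodes, min_bin = 10L) {
  deg <- igraph::degree(graph, v = nodes)
  bin <- floor(log2(pmax(deg, 1L)))
  pools <- list()
  for (b in sort(unique(bin))) {
    width <- 0L
    repeat {
      pool <- nodes[bin >= b - width & bin <= b + width]
      if (length(pool) >= min_bin || width > max(bin)) break
      width <- width + 1L
    }
    pools[[as.character(b)]] <- pool
  }
  list(bin = stats::setNames(bin, nodes), pools = pools)
}

# One degree-matched random replacement for a node set: for each member,
# sample a distinct node from its (widened) degree bin.
sample_matched <- function(dp, members) {
  chosen <- character(length(members))
  for (i in seq_along(members)) {
    pool <- dp$pools[[as.character(dp$bin[[members[i]]])]]
    avail <- setdiff(pool, chosen[seq_len(i - 1L)])
    if (length(avail) == 0L) avail <- pool  # bin exhausted: reuse allowed
    chosen[i] <- if (length(avail) == 1L) avail else sample(avail, 1L)
  }
  chosen
}

#' Network proximity z-score against a degree-matched null
#'
#' Standardizes the observed closest distance `d(X, Y)` against a null in
#' which both X and Y are replaced, each permutation, by random node sets of
#' the same size and matched degree distribution (logarithmic base-2 degree
#' bins, widened when a bin holds fewer than 10 candidates).
#' `z = (d_XY - mu) / sigma` over `n_permutations` null draws. A negative z
#' means the drug's targets sit closer to the disease module than degree-
#' matched chance; z >= 0 means they are separated from it.
#'
#' @inheritParams closest_distance
#' @param n_permutations number of null draws (default 100).
#' @param seed optional integer seed for the null sampling.
#' @return A `proximity_result` list: `d_xy`, `mu`, `sigma`, `z`,
#'   `n_permutations`, `seed`, `flagged` (TRUE when sigma = 0 leaves z
#'   undefined).
#' @export
proximity_zscore <- function(graph, X, Y, n_permutations = 100L,
                             seed = NULL) {
  stopifnot(n_permutations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  xs <- lcc_filter(graph, set_members(X), "X")
  ys <- lcc_filter(graph, set_members(Y), "Y")
  comp <- igraph::components(graph)
  lcc <- igraph::V(graph)$name[comp$membership == which.max(comp$csize)]
  dp <- degree_pools(graph, lcc)

  # one all-pairs BFS over the component, then every permutation is pure
  # matrix indexing
  dm <- igraph::distances(graph, v = lcc, to = lcc)
  mc <- function(xs, ys) mean(apply(dm[ys, xs, drop = FALSE], 1L, min))
  d_obs <- mc(xs, ys)
  null_d <- vapply(seq_len(n_permutations), function(i) {
    mc(sample_matched(dp, xs), sample_matched(dp, ys))
  }, numeric(1L))
  mu <- mean(null_d)
  sigma <- stats::sd(null_d)
  if (n_permutations == 1L) sigma <- 0
  flagged <- !is.finite(sigma) || sigma == 0
  z <- if (flagged) NA_real_ else (d_obs - mu) / sigma
  structure(list(d_xy = d_obs, mu = mu, sigma = sigma, z = z,
                 n_permutations = n_permutations, seed = seed,
                 flagged = flagged),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Network proximity: d = %.3f, null mu = %.3f, sigma = %.3f, z = %s (%d permutations)\n",
              x$d_xy, x$mu, x$sigma,
              if (x$flagged) "undefined (sigma = 0)" else sprintf("%.3f", x$z),
              x$n_permutations))
  invisible(x)
}

#' Separation score between two drug-target modules
#'
#' `s_AB = <d_AB> - (<d_AA> + <d_BB>) / 2`, where `<d_AB>` is the mean over
#' every node of A and B of its nearest hop-distance to the opposite set (a
#' protein shared by both sets contributes 0), and `<d_AA>`, `<d_BB>` are
#' the mean nearest-distinct-neighbor distances within each set (self-
#' distances excluded; a singleton set's within-term is 0 by convention).
#' `s_AB >= 0` marks topologically separated target modules; identical
#' modules always give `s_AB <= 0`.
#'
#' @inheritParams closest_distance
#' @param A,B the two drug-target [protein_set()]s.
#' @return A `separation_result` list: `s_ab`, `d_ab`, `d_aa`, `d_bb`.
#' @export
separation_score <- function(graph, A, B) {
  as_ <- lcc_filter(graph, set_members(A), "A")
  bs <- lcc_filter(graph, set_members(B), "B")
  d_ab <- cross_nearest(graph, as_, bs)
  d_aa <- within_nearest(graph, as_)
  d_bb <- within_nearest(graph, bs)
  structure(list(s_ab = d_ab - (d_aa + d_bb) / 2,
                 d_ab = d_ab, d_aa = d_aa, d_bb = d_bb),
            class = "separation_result")
}

cross_nearest <- function(graph, a, b) {
  dm <- igraph::distances(graph, v = union(a, b), to = union(a, b))
  da <- apply(dm[a, b, drop = FALSE], 1L, min)   # each a to nearest b
  db <- apply(dm[b, a, drop = FALSE], 1L, min)   # each b to nearest a
  mean(c(da, db))
}

within_nearest <- function(graph, a) {
  if (length(a) < 2L) return(0)
  dm <- igraph::distances(graph, v = a, to = a)
  diag(dm) <- Inf
  mean(apply(dm, 1L, min))
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("Separation: s_AB = %.3f (<d_AB> = %.3f, <d_AA> = %.3f, <d_BB> = %.3f)\n",
              x$s_ab, x$d_ab, x$d_aa, x$d_bb))
  invisible(x)
}

#' Classify the exposure pattern of a drug pair on a disease module
#'
#' Computes each drug's proximity z-score to the disease proteins and the
#' separation s_AB between the two target modules, then assigns:
#' \describe{
#'   \item{complementary}{both z < 0 and s_AB >= 0 — both drugs hit the
#'     disease module through topologically distinct target modules; the
#'     pattern predicting an effective combination.}
#'   \item{overlapping}{both z < 0 but s_AB < 0 — both hit the module via
#'     overlapping targets.}
#'   \item{single}{exactly one z < 0.}
#'   \item{non}{neither drug reaches the disease module.}
#' }
#'
#' @inheritParams proximity_zscore
#' @param disease disease-protein [protein_set()].
#' @param drugA,drugB drug-target [protein_set()]s; a drug with no targets
#'   is an error (its network relationship cannot be calculated).
#' @return An `exposure_call` list: `pair`, `z_a`, `z_b`, `s_ab`,
#'   `category`, plus the two `proximity_result`s and the
#'   `separation_result`.
#' @export
classify_exposure <- function(graph, disease, drugA, drugB,
                              n_permutations = 100L, seed = NULL) {
  for (s in list(disease, drugA, drugB)) {
    if (length(set_members(s)) == 0L) {
      stop("a protein set is empty; exposure cannot be calculated")
    }
  }
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  pa <- proximity_zscore(graph, drugA, disease, n_permutations, seeds[[1L]])
  pb <- proximity_zscore(graph, drugB, disease, n_permutations, seeds[[2L]])
  sep <- separation_score(graph, drugA, drugB)
  if (pa$flagged || pb$flagged) {
    stop("proximity z undefined (null sigma = 0); increase permutations")
  }
  hits <- c(pa$z < 0, pb$z < 0)
  category <- if (all(hits)) {
    if (sep$s_ab >= 0) "complementary" else "overlapping"
  } else if (any(hits)) "single" else "non"
  labA <- if (inherits(drugA, "protein_set")) drugA$label else "drugA"
  labB <- if (inherits(drugB, "protein_set")) drugB$label else "drugB"
  structure(list(pair = c(labA, labB), z_a = pa$z, z_b = pb$z,
                 s_ab = sep$s_ab, category = category,
                 proximity_a = pa, proximity_b = pb, separation = sep),
            class = "exposure_call")
}

#' @export
print.exposure_call <- function(x, ...) {
  cat(sprintf("Exposure of pair %s-%s: z_A = %.3f, z_B = %.3f, s_AB = %.3f -> %s\n",
              x$pair[1L], x$pair[2L], x$z_a, x$z_b, x$s_ab, x$category))
  invisible(x)
}

#' Restrict a PPI network to a tissue-expressed subgraph
#'
#' Keeps the subgraph induced by proteins whose median tissue expression is
#' strictly above `threshold` TPM; proteins without an expression value are
#' treated as not expressed and dropped.
#'
#' @param graph PPI graph.
#' @param median_expression named numeric vector, protein -> median TPM.
#' @param threshold TPM cutoff (default 1, strict inequality).
#' @return The induced subgraph, with attributes `n_nodes_before`,
#'   `n_edges_before`, `n_nodes_after`, `n_edges_after`.
#' @export
tissue_filter <- function(graph, median_expression, threshold = 1.0) {
  if (is.null(names(median_expression)) || length(median_expression) == 0L) {
    stop("median_expression must be a non-empty named vector")
  }
  nodes <- igraph::V(graph)$name
  tpm <- median_expression[nodes]
  keep <- nodes[!is.na(tpm) & tpm > threshold]
  if (length(keep) == 0L) {
    stop(sprintf("no protein exceeds the %g TPM threshold; filtered network is empty",
                 threshold))
  }
  sub <- igraph::induced_subgraph(graph, keep)
  attr(sub, "n_nodes_before") <- igraph::vcount(graph)
  attr(sub, "n_edges_before") <- igraph::ecount(graph)
  attr(sub, "n_nodes_after") <- igraph::vcount(sub)
  attr(sub, "n_edges_after") <- igraph::ecount(sub)
  sub
}
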