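# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use naive per-gene / per-node loops so they share no
# code path with the package implementations they check.

# Brute-force sign-product counter for concordance/discordance ratios,
# following the piecewise indicator definitions gene by gene.
oracle_cr_dr <- function(z_dir, d_dir, r_dir, mode) {
  a_cr <- 0L; b_cr <- 0L      # same / opposite direction vs reference
  b_dr <- 0L; a_dr <- 0L      # reversing / mimicking disease, r == 0 only
  for (i in seq_along(z_dir)) {
    zr <- z_dir[i] * r_dir[i]
    if (zr > 0) a_cr <- a_cr + 1L
    if (zr < 0) b_cr <- b_cr + 1L
    if (r_dir[i] == 0) {
      zd <- z_dir[i] * d_dir[i]
      if (zd > 0) a_dr <- a_dr + 1L
      if (zd < 0) b_dr <- b_dr + 1L
    }
  }
  ratio <- function(num, den) {
    if (num + den == 0L) return(NA_real_)
    if (mode == "normalized") num / (num + den)
    else if (den == 0L) Inf else num / den
  }
  list(cr = ratio(a_cr, b_cr), dr = ratio(b_dr, a_dr),
       n_same = a_cr, n_opp = b_cr, n_disc = b_dr, n_conc = a_dr)
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Exhaustive mean over all 3x3 (or largest available) windows.
oracle_window_max <- function(m, w = 3L) {
  wr <- min(w, nrow(m)); wc <- min(w, ncol(m))
  best <- -Inf
  for (i in seq_len(nrow(m) - wr + 1L)) {
    for (j in seq_len(ncol(m) - wc + 1L)) {
      best <- max(best, mean(m[i:(i + wr - 1L), j:(j + wc - 1L)]))
    }
  }
  best
}

# Random signed signature over a fixed universe.
random_signature <- function(genes, p_active = 0.6) {
  dir <- sample(c(-1L, 0L, 1L), length(genes), replace = TRUE,
                prob = c(p_active / 2, 1 - p_active, p_active / 2))
  signed_signature(genes, dir)
}

# Signature from a plain named direction vector.
sig_from_dirs <- function(dirs) {
  signed_signature(names(dirs), as.integer(dirs))
}

# Minimal perturbation panel from a genes x records score matrix.
panel_from_scores <- function(scores, compound, cell_line,
                              experiment = NULL) {
  if (is.null(experiment)) experiment <- paste0("e", seq_along(compound))
  perturbation_panel(scores, data.frame(compound = compound,
                                        cell_line = cell_line,
                                        experiment = experiment,
                                        stringsAsFactors = FALSE))
}

# Small connected Erdos-Renyi-ish graph with named nodes.
random_test_graph <- function(n, p = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Dose matrix straight from monotherapy vectors and a combination block.
dose_matrix_from <- function(y_a, y_b, combo, doses_a = NULL,
                             doses_b = NULL) {
  if (is.null(doses_a)) doses_a <- seq(0, length.out = length(y_a) + 1L)
  if (is.null(doses_b)) doses_b <- seq(0, length.out = length(y_b) + 1L)
  resp <- matrix(0, length(y_a) + 1L, length(y_b) + 1L)
  resp[-1L, 1L] <- y_a
  resp[1L, -1L] <- y_b
  resp[-1L, -1L] <- combo
  dose_response_matrix(resp, doses_a, doses_b)
}
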