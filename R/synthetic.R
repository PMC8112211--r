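# Seeded generators for every pipeline input, each with planted ground
# truth: a negative-binomial case/control cohort with planted DE genes, a
# perturbation panel with planted reverser/mimic compounds, a preferential-
# attachment PPI graph with a two-sub-region disease module and drug target
# sets realizing a chosen exposure scenario, and Hill-curve dose matrices
# with a planted synergy delta.

# Distinct deterministic RNG stream per generator so generators sharing one
# seed do not replay each other's draws (which would entangle, e.g., the
# planted DE genes with the reference mechanism's support).
seed_stream <- function(seed, k) {
  set.seed((as.numeric(seed) + k * 1000003) %% 2147483629)
}

#' Simulation configuration
#'
#' Bundles the generator parameters with their default study conditions:
#' a 1000-gene cohort of 20 case / 20 control samples with 5% of genes
#' planted at |log2FC| = 2 and NB dispersion 0.1; a 100-compound panel over
#' 3 cell lines x 2 experiments with 3 planted reversers; a 1000-node
#' preferential-attachment PPI with two densified 15-node disease
#' sub-regions and 8-protein target sets; checkerboards with 6 non-zero
#' doses per axis from unit-interval Hill monotherapies.
#'
#' @param seed integer seed; identical config + seed gives bit-identical
#'   outputs.
#' @param ... named overrides for any default listed above, e.g.
#'   `n_genes = 500` or `planted_delta = 0.1`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # cohort
    n_genes = 1000L, n_per_arm = 20L, fraction_de = 0.05,
    lfc_magnitude = 2, nb_dispersion = 0.1,
    base_mean_log = log(100), base_mean_sd = 1,
    # perturbation panel
    n_compounds = 100L, n_cell_lines = 3L, n_experiments = 2L,
    n_reversers = 3L, n_mimics = 2L, mechanism_size = 150L,
    mechanism_magnitude = 2, noise_sd = 0.5, cell_line_sd = 0.2,
    # PPI with planted modules
    n_nodes = 1000L, pa_m = 2L, module_size = 15L, target_size = 8L,
    p_within = 0.25, p_between = 0,
    # dose matrices
    doses_a = c(0, 2.5, 5, 10, 20, 40, 80),
    doses_b = c(0, 2.5, 5, 10, 20, 40, 80),
    hill_a = c(ec50 = 60, slope = 1.2),
    hill_b = c(ec50 = 55, slope = 1.5),
    planted_delta = 0, dose_noise_sd = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  counts <- c("n_genes", "n_per_arm", "n_compounds", "n_cell_lines",
              "n_experiments", "n_nodes", "pa_m", "target_size")
  for (f in counts) if (cfg[[f]] < 1L) stop(f, " must be positive")
  for (f in c("fraction_de", "p_within", "p_between")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$dose_noise_sd < 0) stop("dose_noise_sd must be non-negative")
  structure(cfg, class = c("sim_config", "list"))
}

#' Synthetic case/control expression cohort with planted DE genes
#'
#' Negative-binomial counts (mean-dispersion parameterization) around
#' log-normal baseline means; a seeded random subset of genes carries a
#' log2 mean shift of +/- `lfc_magnitude` in the case arm.
#'
#' @param config a [sim_config()].
#' @param seed seed override (default `config$seed`).
#' @return List: `cohort` (an [expression_cohort()]) and `truth`
#'   (data.frame gene, is_de, true_lfc).
#' @export
gen_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  seed_stream(seed, 1L)
  n_g <- config$n_genes
  n_s <- config$n_per_arm
  genes <- sprintf("g%04d", seq_len(n_g))

  n_de <- round(config$fraction_de * n_g)
  if (n_de < 1L) {
    warning("fraction_de * n_genes < 1; no genes planted")
    n_de <- 0L
  }
  planted <- sort(sample.int(n_g, n_de))
  signs <- sample(c(-1, 1), n_de, replace = TRUE)
  lfc <- numeric(n_g)
  if (config$lfc_magnitude != 0) lfc[planted] <- signs * config$lfc_magnitude

  mu0 <- stats::rlnorm(n_g, config$base_mean_log, config$base_mean_sd)
  mu_case <- mu0 * 2^lfc
  size <- 1 / config$nb_dispersion
  ctrl <- matrix(stats::rnbinom(n_g * n_s, mu = mu0, size = size),
                 nrow = n_g)
  case <- matrix(stats::rnbinom(n_g * n_s, mu = mu_case, size = size),
                 nrow = n_g)
  values <- cbind(case, ctrl)
  rownames(values) <- genes
  colnames(values) <- c(sprintf("case%02d", seq_len(n_s)),
                        sprintf("ctrl%02d", seq_len(n_s)))
  cohort <- expression_cohort(values,
                              rep(c("case", "control"), each = n_s))
  truth <- data.frame(gene = genes, is_de = lfc != 0, true_lfc = lfc,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Synthetic perturbation panel with planted compound roles
#'
#' Each compound gets a latent mechanism vector over the disease
#' signature's gene universe; observed profiles are
#' mechanism + cell-line offset + Gaussian noise, one per
#' (cell line, experiment). A reference compound ("REF") carries the
#' reference mechanism. Planted "reverser" compounds oppose the reference
#' on its support and oppose the disease on disease genes the reference
#' misses (low CR, high DR by construction); "mimic" compounds copy the
#' reference mechanism and mimic the disease on the eligible genes (high
#' CR, low DR); the rest carry random mechanisms.
#'
#' @param config a [sim_config()].
#' @param disease disease [signed_signature()] defining the gene universe.
#' @param reference_mechanism optional named numeric mechanism vector for
#'   the reference compound; by default +/- `mechanism_magnitude` on
#'   `mechanism_size` random genes.
#' @param seed seed override.
#' @return List: `panel` (a [perturbation_panel()]), `truth` (data.frame
#'   compound, role), `reference` ("REF").
#' @export
gen_perturbation_panel <- function(config, disease,
                                   reference_mechanism = NULL,
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(disease, "signed_signature"))
  seed_stream(seed, 2L)
  genes <- disease$gene
  n_g <- length(genes)
  if (config$mechanism_size > n_g) {
    stop("mechanism support exceeds the gene universe")
  }
  d_dir <- signature_dirs(disease)
  mag <- config$mechanism_magnitude

  random_mech <- function() {
    m <- numeric(n_g)
    idx <- sample.int(n_g, config$mechanism_size)
    m[idx] <- sample(c(-mag, mag), config$mechanism_size, replace = TRUE)
    m
  }
  if (is.null(reference_mechanism)) {
    r_mech <- random_mech()
  } else {
    r_mech <- numeric(n_g)
    r_mech[match(names(reference_mechanism), genes)] <- reference_mechanism
  }
  r_active <- r_mech != 0
  eligible <- !r_active & d_dir != 0   # disease genes the reference misses

  n_cmp <- config$n_compounds
  if (config$n_reversers + config$n_mimics > n_cmp) {
    stop("more planted reversers + mimics than compounds")
  }
  roles <- rep("background", n_cmp)
  special <- sample.int(n_cmp, config$n_reversers + config$n_mimics)
  roles[special[seq_len(config$n_reversers)]] <- "reverser"
  roles[special[-seq_len(config$n_reversers)]] <- "mimic"
  compounds <- sprintf("cmp%03d", seq_len(n_cmp))

  mech_for <- function(role) {
    if (role == "reverser") {
      m <- numeric(n_g)
      m[r_active] <- -sign(r_mech[r_active]) * mag
      m[eligible] <- -d_dir[eligible] * mag
      m
    } else if (role == "mimic") {
      m <- numeric(n_g)
      m[r_active] <- sign(r_mech[r_active]) * mag
      m[eligible] <- d_dir[eligible] * mag
      m
    } else {
      random_mech()
    }
  }
  mechs <- c(list(REF = r_mech),
             stats::setNames(lapply(roles, mech_for), compounds))

  cls <- sprintf("CL%d", seq_len(config$n_cell_lines))
  cl_offset <- matrix(stats::rnorm(n_g * length(cls), 0, config$cell_line_sd),
                      nrow = n_g, dimnames = list(genes, cls))

  n_rec_per_cmp <- config$n_cell_lines * config$n_experiments
  rec_compound <- rep(names(mechs), each = n_rec_per_cmp)
  rec_cl <- rep(rep(cls, each = config$n_experiments), times = length(mechs))
  rec_exp <- rep(sprintf("exp%d", seq_len(config$n_experiments)),
                 times = length(mechs) * config$n_cell_lines)
  scores <- matrix(0, nrow = n_g, ncol = length(rec_compound),
                   dimnames = list(genes, NULL))
  for (k in seq_along(rec_compound)) {
    scores[, k] <- mechs[[rec_compound[k]]] + cl_offset[, rec_cl[k]] +
      stats::rnorm(n_g, 0, config$noise_sd)
  }
  panel <- perturbation_panel(scores,
                              data.frame(compound = rec_compound,
                                         cell_line = rec_cl,
                                         experiment = rec_exp,
                                         stringsAsFactors = FALSE))
  truth <- data.frame(compound = compounds, role = roles,
                      stringsAsFactors = FALSE)
  list(panel = panel, truth = truth, reference = "REF")
}

#' Synthetic PPI graph with a planted disease module and drug target sets
#'
#' Builds a preferential-attachment base graph (degree-heterogeneous, so
#' degree-matched null sampling is non-trivial), densifies two disjoint
#' disease sub-regions by extra within-region wiring, and places two drug
#' target sets to realize a requested exposure scenario:
#' \describe{
#'   \item{complementary}{each drug's targets drawn from a different
#'     sub-region (both proximal to the disease, modules separated).}
#'   \item{overlapping}{both drugs drawn from the same sub-region.}
#'   \item{single}{drug A in a sub-region, drug B among the nodes farthest
#'     from the disease module.}
#'   \item{non}{both drugs among the farthest nodes.}
#' }
#'
#' @param config a [sim_config()]; `p_between` above 0.1 would merge the
#'   two sub-regions into one module and is rejected.
#' @param scenario one of "complementary", "overlapping", "single", "non".
#' @param seed seed override.
#' @return List: `graph`, `disease`, `drugA`, `drugB` ([protein_set()]s)
#'   and `planted_category` (= `scenario`).
#' @export
gen_ppi_with_modules <- function(config,
                                 scenario = c("complementary", "overlapping",
                                              "single", "non"),
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  if (config$module_size < 1L) stop("module_size must be positive")
  if (2L * config$module_size >= config$n_nodes) {
    stop("disease module sizes must be smaller than the graph")
  }
  if (config$p_between > 0.1) {
    stop("p_between > 0.1 would merge the two disease sub-regions")
  }
  seed_stream(seed, 3L)
  g <- igraph::sample_pa(config$n_nodes, power = 1, m = config$pa_m,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("p%03d", seq_len(config$n_nodes))

  # keep hubs out of the planted modules so module membership, not raw
  # degree, drives proximity
  deg <- igraph::degree(g)
  candidates <- igraph::V(g)$name[rank(-deg, ties.method = "first") > 10L]
  s1 <- sample(candidates, config$module_size)
  # second sub-region: a distinct lobe adjacent to the first (distance 2),
  # so the two lobes form one disease neighborhood with separable parts
  dist_s1 <- apply(igraph::distances(g, v = s1), 2L, min)
  ring_width <- 2L
  repeat {
    ring <- intersect(names(dist_s1)[dist_s1 == ring_width], candidates)
    if (length(ring) >= config$module_size || ring_width > 4L) break
    ring_width <- ring_width + 1L
  }
  if (length(ring) < config$module_size) {
    ring <- setdiff(candidates, s1)
  }
  s2 <- sample(ring, config$module_size)

  wire <- function(g, members, p) {
    pairs <- utils::combn(members, 2L)
    take <- stats::runif(ncol(pairs)) < p
    if (any(take)) g <- igraph::add_edges(g, as.vector(pairs[, take]))
    igraph::simplify(g)
  }
  g <- wire(g, s1, config$p_within)
  g <- wire(g, s2, config$p_within)
  if (config$p_between > 0) {
    cross <- expand.grid(s1, s2, stringsAsFactors = FALSE)
    take <- stats::runif(nrow(cross)) < config$p_between
    if (any(take)) {
      g <- igraph::simplify(
        igraph::add_edges(g, as.vector(t(as.matrix(cross[take, ])))))
    }
  }
  disease_nodes <- c(s1, s2)

  far_pool <- function() {
    d <- igraph::distances(g, v = disease_nodes)
    nearest <- apply(d, 2L, min)
    nearest[!is.finite(nearest)] <- -Inf   # off-component nodes unusable
    pool <- names(sort(nearest, decreasing = TRUE))
    utils::head(pool, max(config$target_size * 4L,
                          round(config$n_nodes / 10)))
  }
  k <- config$target_size
  sets <- switch(scenario,
    complementary = list(A = sample(s1, k), B = sample(s2, k)),
    overlapping   = list(A = sample(s1, k), B = sample(s1, k)),
    single        = list(A = sample(s1, k), B = sample(far_pool(), k)),
    non           = { p <- far_pool(); picks2 <- sample(p, 2L * k)
                      list(A = picks2[seq_len(k)], B = picks2[-seq_len(k)]) })

  list(graph = g,
       disease = protein_set("disease", disease_nodes),
       drugA = protein_set("drugA", sets$A),
       drugB = protein_set("drugB", sets$B),
       planted_category = scenario)
}

#' Synthetic dose-response checkerboard with a planted synergy delta
#'
#' Monotherapy inhibition follows unit-interval Hill curves
#' (`y = (c / ec50)^slope / (1 + (c / ec50)^slope)`); combination cells are
#' the Bliss-independent expectation plus `planted_delta`, then
#' multiplicative Gaussian noise (`sd = dose_noise_sd`) on every treated
#' well, clipped to [0, 1].
#'
#' @param config a [sim_config()] (needs >= 4 non-zero doses per axis).
#' @param seed seed override.
#' @return List: `matrix` (a [dose_response_matrix()]) and `truth`
#'   (`planted_delta`, the noise-free response surface).
#' @export
gen_dose_matrix <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  seed_stream(seed, 4L)
  da <- config$doses_a
  db <- config$doses_b
  if (sum(da > 0) < 4L || sum(db > 0) < 4L) {
    stop("need at least 4 non-zero doses per axis")
  }
  hill <- function(c, p) ifelse(c == 0, 0,
                                (c / p[["ec50"]])^p[["slope"]] /
                                  (1 + (c / p[["ec50"]])^p[["slope"]]))
  ya <- hill(da, config$hill_a)
  yb <- hill(db, config$hill_b)
  clean <- outer(ya, yb, function(a, b) a + b - a * b)
  clean[-1L, -1L] <- clean[-1L, -1L] + config$planted_delta
  clean <- pmin(pmax(clean, 0), 1)

  resp <- clean
  if (config$dose_noise_sd > 0) {
    treated <- row(resp) > 1L | col(resp) > 1L
    noise <- matrix(stats::rnorm(length(resp), 0, config$dose_noise_sd),
                    nrow = nrow(resp))
    resp[treated] <- resp[treated] * (1 + noise[treated])
    resp <- pmin(pmax(resp, 0), 1)
  }
  mat <- dose_response_matrix(resp, da, db)
  list(matrix = mat,
       truth = list(planted_delta = config$planted_delta, clean = clean))
}
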