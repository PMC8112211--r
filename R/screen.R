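# End-to-end screen orchestration: disease signature -> orthogonality
# ranking -> network-based exposure assessment -> synergy scoring, driven by
# a single config (YAML/JSON file or list), with a provenance block so a
# given config + seed reproduces the report byte-for-byte.

#' Read a screen configuration file
#'
#' YAML or JSON with optional blocks `signature`, `rank`, `network`,
#' `synergy`, `simulate`, plus `seed`, `output_dir` and a `stages` block of
#' logical switches. Missing fields fall back to the screen defaults
#' (log2FC threshold 1, FDR 0.1, min_fraction 0.5, correlation 0.7,
#' 100 permutations, top_k 3, TPM 1.0, 3x3 synergy window).
#'
#' @param path path to the config file.
#' @return A named list.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

screen_defaults <- function() {
  list(seed = 1L, output_dir = "screen_out",
       stages = list(signature = TRUE, rank = TRUE,
                     network = TRUE, synergy = TRUE),
       simulate = TRUE,
       signature = list(lfc_threshold = 1, fdr_threshold = 0.1),
       rank = list(reference = "REF", top_k = 3L, mode = "normalized",
                   min_fraction = 0.5),
       network = list(permutations = 100L, scenario = "complementary",
                      tissue_tpm = NULL),
       synergy = list(models = c("bliss", "zip")))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(character(0))
  as.list(tools::md5sum(paths))
}

config_digest <- function(cfg) {
  cfg$output_dir <- NULL  # run location is not part of the configuration
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Validate screen inputs without running the screen
#'
#' Checks that referenced files exist and parse, that the panel and cohort
#' gene universes overlap (hard error when the intersection is empty, a
#' warning entry when the shared genes cover less than half of either
#' universe), and that edge lists are free of duplicate edges (duplicates
#' are noted; the graph reader deduplicates them). Never modifies data.
#'
#' @param config config file path or list (see [read_screen_config()]).
#' @return A `screen_validation` list with character vectors `errors`,
#'   `warnings`, `notes`; zero errors means the screen can run.
#' @export
validate_inputs <- function(config) {
  cfg <- if (is.character(config)) read_screen_config(config) else config
  cfg <- merge_config(screen_defaults(), cfg)
  errors <- character(0); warns <- character(0); notes <- character(0)

  read_try <- function(path, reader, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      errors <<- c(errors, sprintf("%s file not readable: %s", what, path))
      return(NULL)
    }
    tryCatch(reader(path), error = function(e) {
      errors <<- c(errors, sprintf("%s file failed to parse (%s): %s",
                                   what, path, conditionMessage(e)))
      NULL
    })
  }

  cohort <- NULL
  if (!is.null(cfg$signature$expression)) {
    cohort <- tryCatch(
      read_expression_tsv(cfg$signature$expression, cfg$signature$condition),
      error = function(e) {
        errors <<- c(errors, paste("expression cohort:", conditionMessage(e)))
        NULL
      })
  }
  panel <- read_try(cfg$rank$panel, read_panel_tsv, "panel")
  if (!is.null(cohort) && !is.null(panel)) {
    shared <- intersect(rownames(cohort$values), rownames(panel$scores))
    if (length(shared) == 0L) {
      errors <- c(errors, "cohort and panel gene universes do not intersect")
    } else {
      frac <- length(shared) /
        min(nrow(cohort$values), nrow(panel$scores))
      if (frac < 0.5) {
        warns <- c(warns, sprintf(
          "shared genes cover only %.0f%% of the smaller universe",
          100 * frac))
      }
    }
  }
  if (!is.null(cfg$network$edges) && file.exists(cfg$network$edges)) {
    g <- read_try(cfg$network$edges, read_edgelist, "edge list")
    if (!is.null(g)) {
      raw <- utils::read.delim(cfg$network$edges, header = FALSE,
                               stringsAsFactors = FALSE)
      n_dup <- nrow(raw) - igraph::ecount(g)
      if (n_dup > 0L) {
        notes <- c(notes, sprintf(
          "edge list holds %d duplicate/self edge(s); deduplicated on load",
          n_dup))
      }
      sets <- read_try(cfg$network$disease, read_protein_sets, "disease set")
      if (!is.null(sets)) {
        for (s in sets) {
          hit <- length(intersect(s$members, igraph::V(g)$name))
          if (hit == 0L) {
            errors <- c(errors, sprintf(
              "protein set '%s' has no member in the network", s$label))
          }
        }
      }
    }
  } else if (!is.null(cfg$network$edges)) {
    errors <- c(errors, paste("edge list file not readable:",
                              cfg$network$edges))
  }
  for (m in cfg$synergy$matrices) {
    read_try(m, read_dose_matrix_csv, "dose matrix")
  }
  structure(list(errors = errors, warnings = warns, notes = notes),
            class = "screen_validation")
}

#' @export
print.screen_validation <- function(x, ...) {
  cat(sprintf("Input validation: %d error(s), %d warning(s), %d note(s)\n",
              length(x$errors), length(x$warnings), length(x$notes)))
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Run the full drug-combination screen
#'
#' Executes the enabled stages in order. With `simulate: true` (the
#' default) every input is generated by the seeded synthetic generators;
#' otherwise the config's file paths are read. The transcriptomics stage
#' computes the disease signature and ranks library compounds by
#' orthogonality score against the reference; the network stage classifies
#' the exposure pattern of the assessable drug pair(s); the synergy stage
#' scores any dose matrices with the enabled reference models. A stage
#' whose inputs are missing is skipped with an explicit report entry. The
#' report (JSON) and stage tables (TSV) are written under `output_dir`.
#'
#' @param config config file path or list; see [read_screen_config()].
#' @return A `screen_report` list: `signature_summary`, `ranking`,
#'   `exposure`, `synergy`, `skipped`, `provenance`, `output_dir`.
#' @export
run_screen <- function(config) {
  cfg <- if (is.character(config)) read_screen_config(config) else config
  cfg <- merge_config(screen_defaults(), cfg)
  enabled <- vapply(cfg$stages, isTRUE, logical(1L))
  if (!any(enabled)) stop("all stages are disabled; nothing to run")
  if (!isTRUE(cfg$stages$signature)) {
    stop("the transcriptomics (signature) stage must be enabled")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  skipped <- list()
  simcfg <- sim_config(seed)
  input_files <- character(0)

  note_skip <- function(stage, why) {
    message(sprintf("stage '%s' skipped: %s", stage, why))
    skipped[[stage]] <<- why
  }

  ## --- signature stage -------------------------------------------------
  message("stage 'signature': computing disease signature")
  if (isTRUE(cfg$simulate)) {
    cohort <- gen_cohort(simcfg, seed = seed)$cohort
  } else {
    input_files <- c(input_files, cfg$signature$expression,
                     cfg$signature$condition)
    cohort <- read_expression_tsv(cfg$signature$expression,
                                  cfg$signature$condition)
  }
  disease <- compute_disease_signature(cohort,
                                       cfg$signature$lfc_threshold,
                                       cfg$signature$fdr_threshold)
  write_signature_tsv(disease, file.path(cfg$output_dir,
                                         "disease_signature.tsv"))
  sig_summary <- list(n_genes = nrow(disease),
                      n_up = attr(disease, "n_up"),
                      n_down = attr(disease, "n_down"))

  ## --- ranking stage ---------------------------------------------------
  ranking <- NULL
  if (isTRUE(cfg$stages$rank)) {
    message("stage 'rank': scoring compound orthogonality")
    panel <- NULL
    if (isTRUE(cfg$simulate)) {
      sim_panel <- gen_perturbation_panel(simcfg, disease, seed = seed + 1L)
      panel <- sim_panel$panel
      cfg$rank$reference <- sim_panel$reference
    } else if (!is.null(cfg$rank$panel)) {
      input_files <- c(input_files, cfg$rank$panel)
      panel <- read_panel_tsv(cfg$rank$panel)
    }
    if (is.null(panel)) {
      note_skip("rank", "no perturbation panel provided")
    } else {
      ranking <- rank_candidates(panel, cfg$rank$reference, disease,
                                 top_k = cfg$rank$top_k,
                                 mode = cfg$rank$mode)
      write_ranking_tsv(ranking, file.path(cfg$output_dir, "ranking.tsv"))
    }
  }

  ## --- network stage ---------------------------------------------------
  exposure <- list()
  if (isTRUE(cfg$stages$network)) {
    message("stage 'network': exposure classification")
    net <- NULL
    if (isTRUE(cfg$simulate)) {
      sim_net <- gen_ppi_with_modules(simcfg, cfg$network$scenario,
                                      seed = seed + 2L)
      net <- list(graph = sim_net$graph, disease = sim_net$disease,
                  pairs = list(list(A = sim_net$drugA, B = sim_net$drugB)))
    } else if (!is.null(cfg$network$edges)) {
      input_files <- c(input_files, cfg$network$edges,
                       cfg$network$disease, cfg$network$targets)
      graph <- read_edgelist(cfg$network$edges)
      dsets <- read_protein_sets(cfg$network$disease)
      tsets <- if (is.null(cfg$network$targets)) list()
               else read_protein_sets(cfg$network$targets)
      pairs <- list()
      refs <- cfg$rank$reference
      cands <- if (is.null(ranking)) character(0) else ranking$top$compound
      for (ref in refs) for (cand in cands) {
        if (!is.null(tsets[[ref]]) && !is.null(tsets[[cand]])) {
          pairs[[length(pairs) + 1L]] <- list(A = tsets[[ref]],
                                              B = tsets[[cand]])
        } else {
          exposure[[paste(ref, cand, sep = "-")]] <-
            list(pair = c(ref, cand), category = "not assessable",
                 reason = "missing drug-target set")
        }
      }
      net <- list(graph = graph, disease = dsets[[1L]], pairs = pairs)
    }
    if (is.null(net)) {
      note_skip("network", "no interaction network provided")
    } else {
      if (!is.null(cfg$network$tissue_tpm) &&
          !is.null(cfg$network$expression)) {
        expr <- utils::read.delim(cfg$network$expression,
                                  stringsAsFactors = FALSE)
        tpm <- stats::setNames(expr[[2L]], expr[[1L]])
        net$graph <- tissue_filter(net$graph, tpm, cfg$network$tissue_tpm)
      }
      for (i in seq_along(net$pairs)) {
        p <- net$pairs[[i]]
        call <- classify_exposure(net$graph, net$disease, p$A, p$B,
                                  n_permutations = cfg$network$permutations,
                                  seed = seed + 10L + i)
        exposure[[paste(call$pair, collapse = "-")]] <-
          list(pair = call$pair, z_a = call$z_a, z_b = call$z_b,
               s_ab = call$s_ab, category = call$category)
      }
    }
  }

  ## --- synergy stage ---------------------------------------------------
  synergy <- list()
  if (isTRUE(cfg$stages$synergy)) {
    message("stage 'synergy': dose-matrix scoring")
    mats <- list()
    if (isTRUE(cfg$simulate)) {
      mats[["simulated"]] <- gen_dose_matrix(simcfg, seed = seed + 3L)$matrix
    } else {
      for (m in cfg$synergy$matrices) {
        input_files <- c(input_files, m)
        mats[[basename(m)]] <- read_dose_matrix_csv(
          m, scale = cfg$synergy$scale %||% "inhibition")
      }
    }
    if (length(mats) == 0L) {
      note_skip("synergy", "no dose matrices provided")
    } else {
      for (nm in names(mats)) {
        res <- list()
        if ("bliss" %in% cfg$synergy$models) {
          b <- bliss_delta(mats[[nm]])
          res$bliss <- list(synergy_score = b$synergy_score,
                            most_synergistic_area = b$most_synergistic_area)
          utils::write.table(
            b$delta, file.path(cfg$output_dir,
                               paste0(nm, "_bliss_delta.tsv")),
            sep = "\t", quote = FALSE)
        }
        if ("zip" %in% cfg$synergy$models) {
          z <- zip_delta(mats[[nm]])
          res$zip <- list(synergy_score = z$synergy_score,
                          most_synergistic_area = z$most_synergistic_area)
        }
        synergy[[nm]] <- res
      }
    }
  }

  provenance <- list(
    tool = "dcscreen",
    version = as.character(utils::packageVersion("dcscreen")),
    seed = seed,
    config_digest = config_digest(cfg),
    input_digests = md5_of(unlist(input_files)))

  report <- structure(
    list(signature_summary = sig_summary,
         ranking = if (is.null(ranking)) NULL else list(
           reference = ranking$reference,
           top = ranking$top[, c("compound", "cr", "dr", "os")],
           n_valid = nrow(ranking$table),
           n_flagged = nrow(ranking$flagged)),
         exposure = exposure,
         synergy = synergy,
         skipped = skipped,
         provenance = provenance,
         output_dir = cfg$output_dir),
    class = "screen_report")
  jsonlite::write_json(unclass(report),
                       file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.screen_report <- function(x, ...) {
  cat("Drug-combination screen report\n")
  cat(sprintf("  disease signature: %d active genes (%d up, %d down) of %d tested\n",
              x$signature_summary$n_up + x$signature_summary$n_down,
              x$signature_summary$n_up, x$signature_summary$n_down,
              x$signature_summary$n_genes))
  if (!is.null(x$ranking)) {
    cat(sprintf("  ranking vs '%s': top candidates %s\n",
                x$ranking$reference,
                paste(x$ranking$top$compound, collapse = ", ")))
  }
  for (nm in names(x$exposure)) {
    e <- x$exposure[[nm]]
    cat(sprintf("  exposure %s: %s\n", nm, e$category))
  }
  for (nm in names(x$synergy)) {
    s <- x$synergy[[nm]]
    for (model in names(s)) {
      cat(sprintf("  synergy %s [%s]: score %.2f, MSA %.2f\n", nm, model,
                  s[[model]]$synergy_score,
                  s[[model]]$most_synergistic_area))
    }
  }
  for (nm in names(x$skipped)) {
    cat(sprintf("  stage '%s' skipped: %s\n", nm, x$skipped[[nm]]))
  }
  cat("  report written to ", file.path(x$output_dir, "report.json"), "\n",
      sep = "")
  invisible(x)
}
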