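# Disease signature, compound TCS and reference-signature construction.

make_cohort <- function(case, ctrl, genes = NULL) {
  v <- cbind(case, ctrl)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(v)))
  rownames(v) <- genes
  colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  expression_cohort(v, rep(c("case", "control"),
                           c(ncol(case), ncol(ctrl))))
}

test_that("no differential signal gives an empty signature", {
  set.seed(1)
  base <- matrix(rpois(200 * 8, 50), nrow = 200)
  cohort <- make_cohort(base[, 1:4], base[, 5:8])
  sig <- compute_disease_signature(cohort)
  expect_s3_class(sig, "signed_signature")
  expect_equal(n_active(sig), 0)
})

test_that("both thresholds are strict: a gene exactly on either boundary is excluded", {
  sim <- gen_cohort(sim_config(3))
  sig <- compute_disease_signature(sim$cohort, 1, 0.1)
  stats <- attr(sig, "stats")
  active <- stats$gene[sig$direction != 0]
  expect_gt(length(active), 0)
  g <- active[1L]
  # re-test with the cutoffs set exactly to this gene's realized values:
  # strict inequalities must now exclude it
  lfc_g <- abs(stats$log2fc[stats$gene == g])
  sig_lfc <- compute_disease_signature(sim$cohort, lfc_threshold = lfc_g,
                                       fdr_threshold = 0.1)
  expect_equal(sig_lfc$direction[sig_lfc$gene == g], 0L)
  padj_g <- attr(sig, "stats")$padj[stats$gene == g]
  sig_fdr <- compute_disease_signature(sim$cohort, 1,
                                       fdr_threshold = padj_g)
  expect_equal(sig_fdr$direction[sig_fdr$gene == g], 0L)
})

test_that("planted DE genes are recovered at the study conditions (seed 7)", {
  sim <- gen_cohort(sim_config(7))
  sig <- compute_disease_signature(sim$cohort)
  recovered <- sum(sig$direction != 0 & sim$truth$is_de)
  expect_equal(recovered, 50)        # frozen from one oracle run
  expect_gte(recovered, 45)
  # recovered directions match the planted fold-change signs
  idx <- sig$direction != 0
  expect_true(all(sig$direction[idx] == sign(sim$truth$true_lfc[idx])))
})

test_that("a missing condition and constant rows are handled as specified", {
  v <- matrix(rpois(40, 20), nrow = 10,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  all_case <- expression_cohort(v, rep("case", 4))
  expect_error(compute_disease_signature(all_case), "control")

  sim <- gen_cohort(sim_config(1, n_genes = 50L, n_per_arm = 4L))
  cohort <- sim$cohort
  cohort$values[1L, ] <- 7          # constant row
  expect_warning(sig <- compute_disease_signature(cohort), "constant")
  expect_false(cohort$values[1L, 1L] < 0)
  expect_false(rownames(cohort$values)[1L] %in% sig$gene)
})

test_that("relaxing both thresholds calls every gene the test can call", {
  sim <- gen_cohort(sim_config(5, n_genes = 200L))
  sig <- compute_disease_signature(sim$cohort, lfc_threshold = 1e-9,
                                   fdr_threshold = 1)
  stats <- attr(sig, "stats")
  should <- abs(stats$log2fc) > 1e-9 & stats$padj < 1
  expect_equal(sig$direction != 0, should)
  expect_gt(mean(should), 0.9)
})

test_that("null-cohort false discoveries stay controlled at the BH level", {
  # complete null: every call is false; BH at 0.1 with the fold-change
  # filter should leave the mean false-discovery proportion far below 0.2
  fdp <- vapply(1:60, function(s) {
    sim <- gen_cohort(sim_config(s, lfc_magnitude = 0, n_genes = 300L))
    sig <- compute_disease_signature(sim$cohort)
    n_called <- n_active(sig)
    if (n_called == 0) 0 else 1
  }, numeric(1))
  expect_lte(mean(fdp), 0.2)
})

test_that("TCS majority rule, support cap and ties follow the consensus definition", {
  genes <- c("gA", "gB", "gC")
  # 3 cell lines, 1 experiment each; gA up everywhere, gB split, gC absent
  scores <- matrix(c( 2,  2,  2,
                      1, -1,  0,
                      0,  0,  0), nrow = 3, byrow = TRUE,
                   dimnames = list(genes, NULL))
  panel <- panel_from_scores(scores, rep("cpd", 3), c("c1", "c2", "c3"))
  tcs <- compute_tcs(panel, "cpd")
  expect_equal(tcs$direction, c(1L, 0L, 0L))
  expect_equal(tcs$support, c(3L, 0L, 0L))   # max support = n cell lines

  # 5 cell lines with calls (+, +, +, -, 0): majority +, support 3
  s5 <- matrix(c(1, 1, 1, -1, 0), nrow = 1,
               dimnames = list("g1", NULL))
  p5 <- panel_from_scores(s5, rep("cpd", 5), paste0("c", 1:5))
  t5 <- compute_tcs(p5, "cpd")
  expect_equal(t5$direction, 1L)
  expect_equal(t5$support, 3L)

  expect_error(compute_tcs(panel, "nope"), "not in panel")
})

test_that("TCS is invariant to record order and cell-line labels, and flips with sign", {
  set.seed(42)
  scores <- matrix(rnorm(50 * 6), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  cls <- rep(c("c1", "c2", "c3"), each = 2)
  exps <- rep(c("e1", "e2"), 3)
  panel <- panel_from_scores(scores, rep("cpd", 6), cls, exps)
  tcs <- compute_tcs(panel, "cpd")

  perm <- sample(6)
  shuffled <- panel_from_scores(scores[, perm], rep("cpd", 6),
                                cls[perm], exps[perm])
  expect_equal(compute_tcs(shuffled, "cpd"), tcs)

  relabeled <- panel_from_scores(scores, rep("cpd", 6),
                                 sub("c", "line_", cls), exps)
  expect_equal(compute_tcs(relabeled, "cpd")$direction, tcs$direction)
  expect_equal(compute_tcs(relabeled, "cpd")$support, tcs$support)

  flipped <- panel_from_scores(-scores, rep("cpd", 6), cls, exps)
  tflip <- compute_tcs(flipped, "cpd")
  expect_equal(tflip$direction, -tcs$direction)
  expect_equal(tflip$support, tcs$support)
})

test_that("per-experiment threshold zeroes weak cell-line calls", {
  scores <- matrix(c(0.2, 0.2, 2), nrow = 1,
                   dimnames = list("g1", NULL))
  panel <- panel_from_scores(scores, rep("cpd", 3), c("c1", "c2", "c3"))
  expect_equal(compute_tcs(panel, "cpd")$support, 3L)
  weak <- compute_tcs(panel, "cpd", per_experiment_threshold = 1)
  expect_equal(weak$support, 1L)      # only the strong cell line calls
  expect_equal(weak$direction, 1L)
})

test_that("reference signature requires the agreeing fraction with strict-majority ties", {
  unan <- panel_from_scores(matrix(c(1, 2, 1, 3), nrow = 1,
                                   dimnames = list("g1", NULL)),
                            rep("ref", 4), rep("pc3", 4))
  r <- compute_reference_signature(unan, "ref")
  expect_equal(r$direction, 1L)
  expect_equal(r$support, 4L)

  split <- panel_from_scores(matrix(c(1, 1, -1, -1), nrow = 1,
                                    dimnames = list("g1", NULL)),
                             rep("ref", 4), rep("pc3", 4))
  expect_equal(compute_reference_signature(split, "ref")$direction, 0L)

  six <- panel_from_scores(matrix(c(1, 1, 1, 1, -1, 0), nrow = 1,
                                  dimnames = list("g1", NULL)),
                           rep("ref", 6), rep("pc3", 6))
  r6 <- compute_reference_signature(six, "ref")
  expect_equal(r6$direction, 1L)     # 4/6 >= 0.5
  expect_equal(r6$support, 4L)

  expect_error(
    compute_reference_signature(six, "ref", cell_line_filter = "du145"),
    "cell-line filter")
})

test_that("signature TSV round-trips losslessly", {
  sim <- gen_cohort(sim_config(2, n_genes = 100L, n_per_arm = 5L))
  sig <- compute_disease_signature(sim$cohort)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_equal(back$gene, sig$gene)
  expect_equal(back$direction, sig$direction)
  expect_equal(back$support, sig$support)
  expect_equal(back$magnitude, sig$magnitude, tolerance = 1e-12)
})
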