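# CR, DR, OS and the candidate ranking / correlation-network layer.

test_that("orthogonality score matches its closed form", {
  expect_equal(orthogonality_score(1, 0), 0, tolerance = 1e-12)
  expect_equal(orthogonality_score(0, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(orthogonality_score(0.25, 0.5), sqrt(0.8125),
               tolerance = 1e-12)
  expect_error(orthogonality_score(Inf, 0.5), "finite")
  expect_error(orthogonality_score(0.5, NA_real_), "finite")
})

test_that("concordance ratio counts sign products on the shared universe", {
  genes <- c("g1", "g2", "g3", "g4")
  z <- sig_from_dirs(setNames(c(1L, -1L, 1L, 0L), genes))
  r <- sig_from_dirs(setNames(c(1L, 1L, -1L, 1L), genes))
  norm <- concordance_ratio(z, r, "normalized")
  expect_equal(norm$n_same, 1L)
  expect_equal(norm$n_opp, 2L)
  expect_equal(norm$cr, 1 / 3)
  expect_equal(concordance_ratio(z, r, "as_printed")$cr, 0.5)

  expect_equal(concordance_ratio(r, r)$cr, 1)          # identical
  neg <- sig_from_dirs(setNames(-c(1L, 1L, -1L, 1L), genes))
  expect_equal(concordance_ratio(neg, r)$cr, 0)        # fully opposed
  # as-printed with no opposing genes: +Inf sentinel, flagged
  ap <- concordance_ratio(r, r, "as_printed")
  expect_true(is.infinite(ap$cr) && ap$flagged)
})

test_that("discordance ratio is confined to disease genes the reference misses", {
  genes <- c("g1", "g2", "g3")
  d <- sig_from_dirs(setNames(c(1L, 1L, -1L), genes))
  r <- sig_from_dirs(setNames(c(0L, 1L, 0L), genes))
  z <- sig_from_dirs(setNames(c(-1L, 1L, 1L), genes))
  res <- discordance_ratio(z, d, r)
  expect_equal(res$n_disc, 2L)
  expect_equal(res$dr, 1)          # full reversal on both eligible genes

  mimic <- discordance_ratio(d, d, r)
  expect_equal(mimic$dr, 0)        # drug mimics the disease

  r_all <- sig_from_dirs(setNames(c(1L, 1L, 1L), genes))
  blocked <- discordance_ratio(z, d, r_all)
  expect_true(blocked$flagged)     # no reference-missing gene left
  expect_true(is.na(blocked$dr))
})

test_that("CR/DR agree exactly with a brute-force sign-product counter", {
  set.seed(99)
  for (rep in 1:50) {
    genes <- sprintf("g%d", seq_len(sample(5:20, 1)))
    z <- random_signature(genes)
    d <- random_signature(genes)
    r <- random_signature(genes)
    if (n_active(r) == 0 || n_active(d) == 0) next
    for (mode in c("normalized", "as_printed")) {
      want <- oracle_cr_dr(z$direction, d$direction, r$direction, mode)
      got_cr <- concordance_ratio(z, r, mode)
      got_dr <- discordance_ratio(z, d, r, mode)
      expect_identical(got_cr$n_same, want$n_same)
      expect_identical(got_cr$n_opp, want$n_opp)
      expect_equal(got_cr$cr, want$cr)
      expect_identical(got_dr$n_disc, want$n_disc)
      expect_identical(got_dr$n_conc, want$n_conc)
      expect_equal(got_dr$dr, want$dr)
    }
  }
})

test_that("ratios depend on signs only, and negating z complements both", {
  set.seed(7)
  genes <- sprintf("g%d", 1:30)
  z <- random_signature(genes); d <- random_signature(genes)
  r <- random_signature(genes)
  scaled <- signed_signature(genes, z$direction,
                             magnitude = z$direction * 7.5,
                             support = z$support * 3L)
  expect_equal(concordance_ratio(scaled, r)$cr, concordance_ratio(z, r)$cr)
  expect_equal(discordance_ratio(scaled, d, r)$dr,
               discordance_ratio(z, d, r)$dr)

  zneg <- signed_signature(genes, -z$direction)
  cr <- concordance_ratio(z, r)$cr
  dr <- discordance_ratio(z, d, r)$dr
  expect_equal(concordance_ratio(zneg, r)$cr, 1 - cr)
  expect_equal(discordance_ratio(zneg, d, r)$dr, 1 - dr)

  # counts never exceed the overlap of active genes
  got <- concordance_ratio(z, r)
  expect_lte(got$n_same + got$n_opp,
             sum(z$direction != 0 & r$direction != 0))
})

test_that("OS is monotone in CR (decreasing) and DR (increasing)", {
  crs <- seq(0, 1, 0.1)
  expect_true(all(diff(orthogonality_score(crs, 0.4)) <= 0))
  drs <- seq(0, 1, 0.1)
  expect_true(all(diff(orthogonality_score(0.4, drs)) >= 0))
})

test_that("ranking orders by OS with DR-then-id tie-breaks, deterministically", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(11)
  d_dir <- sample(c(-1L, 1L), 40, replace = TRUE)
  disease <- sig_from_dirs(setNames(d_dir, genes))
  r_mech <- c(rep(2, 10), rep(0, 30))
  # two identical reversers (tie on OS and DR -> lexicographic id) plus a
  # mimic of the reference
  rev_mech <- c(-r_mech[1:10], -2 * d_dir[11:40])
  mechs <- list(REF = r_mech, cmpB = rev_mech, cmpA = rev_mech,
                cmpC = c(r_mech[1:10], 2 * d_dir[11:40]))
  scores <- do.call(cbind, rep(mechs, each = 2))
  rownames(scores) <- genes
  panel <- panel_from_scores(scores, rep(names(mechs), each = 2),
                             rep(c("c1", "c2"), 4),
                             rep(c("e1", "e2"), 4))
  rk <- rank_candidates(panel, "REF", disease, top_k = 3)
  expect_equal(rk$top$compound, c("cmpA", "cmpB", "cmpC"))
  expect_equal(rk$top$os[1], rk$top$os[2])
  expect_equal(rk$table$os, sort(rk$table$os, decreasing = TRUE))
  # permutation of valid inputs, bit-identical on rerun
  expect_setequal(rk$table$compound, c("cmpA", "cmpB", "cmpC"))
  expect_identical(rank_candidates(panel, "REF", disease, top_k = 3), rk)

  expect_warning(rank_candidates(panel, "REF", disease, top_k = 10),
                 "top_k")
})

test_that("planted reversers rise to the top of the ranking", {
  for (s in 1:3) {
    cfg <- sim_config(s)
    sim <- gen_cohort(cfg)
    disease <- compute_disease_signature(sim$cohort)
    pan <- gen_perturbation_panel(cfg, disease)
    rk <- rank_candidates(pan$panel, pan$reference, disease)
    planted <- pan$truth$compound[pan$truth$role == "reverser"]
    expect_setequal(rk$top$compound, planted)
  }
})

test_that("correlation network links duplicate signatures and cuts anti-correlated ones", {
  set.seed(11)
  genes <- sprintf("g%03d", 1:500)
  a <- random_signature(genes)
  indep <- random_signature(genes)
  net <- tcs_correlation_network(list(a = a, dup = a, other = indep))
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(unlist(net$edges[1, c("i", "j")]), c("a", "dup"))
  expect_equal(net$clusters[["a"]], net$clusters[["dup"]])
  # oracle: direct correlation of the direction x support vectors
  va <- as.numeric(a$direction) * a$support
  vo <- as.numeric(indep$direction) * indep$support
  expect_equal(net$correlation["a", "other"], cor(va, vo))
  expect_lt(net$correlation["a", "other"], 0.7)

  aneg <- signed_signature(genes, -a$direction)
  net2 <- tcs_correlation_network(list(a = a, neg = aneg))
  expect_equal(net2$correlation["a", "neg"], -1)
  expect_equal(nrow(net2$edges), 0L)

  flat <- signed_signature(genes, rep(0L, 500))
  expect_warning(tcs_correlation_network(list(a = a, b = indep, flat = flat)),
                 "zero-variance")
})
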