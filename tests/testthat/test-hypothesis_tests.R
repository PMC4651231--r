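# a tiny gene table with chosen lengths / theta values, in code
mini_genes <- function(lengths, thetas, syn_sites = NULL) {
  n <- length(lengths)
  cds <- vapply(lengths, function(L)
    paste(c("ATG", rep("CTG", L / 3 - 1)), collapse = ""), character(1))
  starts <- cumsum(c(10, utils::head(lengths, -1) + 10))
  g <- gene_table(sprintf("g%02d", seq_len(n)), "chr", starts,
                  starts + lengths, "+", cds, theta_s = thetas)
  if (!is.null(syn_sites)) g$syn_sites <- syn_sites
  g
}

test_that("rate models weight genes as specified, ordered by theta_s", {
  g <- mini_genes(c(300, 900), c(0.02, 0.01))
  m <- build_rate_model(g, "length_null")
  # ordering ascends in theta_s: g02 (0.01) before g01 (0.02)
  expect_identical(m$gene_ids, c("g02", "g01"))
  expect_equal(m$weights, c(0.75, 0.25))

  g3 <- mini_genes(c(300, 300, 300), c(0.001, 0.002, 0.007))
  m3 <- build_rate_model(g3, "theta_per_gene")
  expect_equal(m3$weights, c(0.1, 0.2, 0.7))

  # equal theta: theta_per_site degenerates to syn_sites_null
  g4 <- mini_genes(c(300, 600, 900), c(0.01, 0.01, 0.01))
  expect_equal(build_rate_model(g4, "theta_per_site")$weights,
               build_rate_model(g4, "syn_sites_null")$weights)

  g4$theta_s[2] <- NA
  expect_error(build_rate_model(g4, "theta_per_site"), "g02")
  expect_equal(sum(build_rate_model(g3, "length_null")$weights), 1,
               tolerance = 1e-12)
})

test_that("theta ties are broken by gene_id for a total order", {
  g <- mini_genes(c(300, 300, 300), c(0.01, 0.01, 0.005))
  m <- build_rate_model(g, "length_null")
  expect_identical(m$gene_ids, c("g03", "g01", "g02"))
})

test_that("observed curves are cumulative proportions over the ordering", {
  g <- mini_genes(c(300, 300, 300), c(0.001, 0.002, 0.007))
  m <- build_rate_model(g, "length_null")
  counts <- c(g01 = 2, g02 = 3, g03 = 5)
  oc <- observed_curve(counts, m)
  expect_equal(oc$cumulative, c(0.2, 0.5, 1.0))
  expect_equal(observed_curve(c(g01 = 0, g02 = 0, g03 = 7), m)$cumulative,
               c(0, 0, 1))
  expect_error(observed_curve(c(g01 = 0, g02 = 0, g03 = 0), m), ">= 1")
  expect_error(observed_curve(c(gX = 3), m), "absent from the model")
})

test_that("ks_compare: identity, hand-computed D, and the printed tail", {
  g <- mini_genes(c(300, 600, 900, 1200), c(0.001, 0.004, 0.002, 0.01))
  for (mode in RATE_MODES) {
    m <- build_rate_model(g, mode)
    # observed curve equal to the model CDF: D = 0, p = 1
    fake_counts <- stats::setNames(m$weights * 1000, m$gene_ids)
    res <- ks_compare(observed_curve(fake_counts, m), m, 1000)
    expect_equal(res$D, 0)
    expect_equal(res$p_asymptotic, 1)
  }

  # two equal-weight genes, all 10 substitutions in the first:
  # model CDF (0.5, 1), observed (1, 1) -> D = 0.5
  g2 <- mini_genes(c(300, 300), c(0.001, 0.002))
  m2 <- build_rate_model(g2, "length_null")
  res2 <- ks_compare(observed_curve(c(g01 = 10, g02 = 0), m2), m2, 10)
  expect_equal(res2$D, 0.5)

  # the large-sample tail: D = 0.244 at n = 1069 is astronomically small
  lam <- (sqrt(1069) + 0.12 + 0.11 / sqrt(1069)) * 0.244
  expect_lt(2 * exp(-2 * lam^2), 1e-15)  # leading term of the series
  fake <- observed_curve(c(g01 = 10, g02 = 0), m2)
  # reuse the internal via a result at that D and n
  res3 <- ks_compare(fake, m2, 1069)
  expect_identical(res3$n, 1069L)
  # monotone: larger D gives smaller asymptotic p at fixed n
  p_small <- ks_compare(observed_curve(c(g01 = 6, g02 = 4), m2), m2,
                        100)$p_asymptotic
  p_large <- ks_compare(observed_curve(c(g01 = 10, g02 = 0), m2), m2,
                        100)$p_asymptotic
  expect_lt(p_large, p_small)

  # ordering mismatch is an error
  g_alt <- mini_genes(c(300, 300), c(0.002, 0.001))
  m_alt <- build_rate_model(g_alt, "length_null")
  expect_error(ks_compare(fake, m_alt, 10), "orderings differ")
})

test_that("asymptotic tail at D = 0.244, n = 1069 is below 1e-15", {
  g2 <- mini_genes(c(300, 300), c(0.001, 0.002))
  m2 <- build_rate_model(g2, "length_null")
  # construct an observed curve with D exactly 0.244: weights (0.5, 0.5),
  # observed first-gene proportion 0.744
  oc <- observed_curve(c(g01 = 744, g02 = 256), m2)
  res <- ks_compare(oc, m2, 1069)
  expect_equal(res$D, 0.244)
  expect_lt(res$p_asymptotic, 1e-15)
})

test_that("monte_carlo_pvalue: degenerate cases and reproducibility", {
  g <- mini_genes(c(300, 600), c(0.001, 0.002))
  m <- build_rate_model(g, "length_null")
  expect_equal(monte_carlo_pvalue(m, 10, 0, reps = 99, seed = 1), 1)
  expect_equal(monte_carlo_pvalue(m, 10, 1.0001, reps = 99, seed = 1),
               1 / 100)
  p1 <- monte_carlo_pvalue(m, 20, 0.3, reps = 500, seed = 42)
  p2 <- monte_carlo_pvalue(m, 20, 0.3, reps = 500, seed = 42)
  expect_identical(p1, p2)
})

test_that("monte_carlo_pvalue matches exhaustive enumeration", {
  # 2 equal-weight genes, n = 10, D_obs = 0.5: exact tail enumerable over
  # the 11 outcomes of Binomial(10, 1/2)
  g <- mini_genes(c(300, 300), c(0.001, 0.002))
  m <- build_rate_model(g, "length_null")
  p_exact <- exact_ks_tail(m, 10, 0.5)
  # independent check of the enumeration itself: |k/10 - 1/2| >= 0.5
  # requires k = 0 or 10... plus interior points where |cum - cdf| >= .5;
  # only gene-1 term matters: P(|B/10 - .5| >= .5) = 2 * (1/2)^10
  expect_equal(p_exact, stats::pbinom(0, 10, 0.5) +
                 stats::pbinom(9, 10, 0.5, lower.tail = FALSE))
  reps <- 2000
  p_mc <- monte_carlo_pvalue(m, 10, 0.5, reps = reps, seed = 7)
  ci <- stats::qbinom(c(0.005, 0.995), reps, p_exact)
  hits <- p_mc * (reps + 1) - 1
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("subgroup tests split by lineage and skip empty groups", {
  sc <- small_cohort(n_genes = 20, n_sub = 60, seed = 77)
  ann <- annotate_mutations(sc$mutations, sc$genes, genome = sc$genome)
  core <- core_synonymous_set(ann)
  m <- build_rate_model(sc$genes, "length_null")
  res <- subgroup_tests(core, sc$genes, m)
  expect_setequal(names(res), unique(core$lineage_class))
  single <- core[core$lineage_class == "MMR_hypermutator", ]
  res1 <- subgroup_tests(single, sc$genes, m)
  expect_identical(names(res1), "MMR_hypermutator")
  expect_warning(
    subgroup_tests(single, sc$genes, m,
                   groups = c("MMR_hypermutator", "nonmutator")),
    "nonmutator")
})

test_that("spectrum summaries conserve totals", {
  empty <- spectrum_summary(
    data.frame(clone_id = character(0), spectrum = character(0)))
  expect_identical(nrow(empty), 0L)

  one_each <- data.frame(clone_id = "c1", spectrum = SPECTRUM_CLASSES,
                         stringsAsFactors = FALSE)
  tab <- spectrum_summary(one_each)
  expect_identical(unname(unlist(tab[1, SPECTRUM_CLASSES])),
                   rep(1L, 6))
  expect_identical(tab$total, 6L)

  sc <- small_cohort(n_genes = 20, n_sub = 100, seed = 13)
  ann <- annotate_mutations(sc$mutations, sc$genes, genome = sc$genome)
  tab2 <- spectrum_summary(ann)
  expect_identical(sum(tab2$total), nrow(ann))
  expect_identical(as.integer(rowSums(tab2[SPECTRUM_CLASSES])), tab2$total)
})

test_that("discrete KS against the generating model is conservative", {
  # scaled-down calibration: 40 seeds at n = 200 over 50 genes; the
  # full-scale version is an acceptance criterion
  sc <- small_cohort(n_genes = 50, n_sub = 10, seed = 9)
  m <- build_rate_model(sc$genes, "length_null")
  rej <- 0L
  for (s in 1:40) {
    counts <- with_seed(s, as.vector(stats::rmultinom(1, 200, m$weights)))
    names(counts) <- m$gene_ids
    p <- ks_compare(observed_curve(counts, m), m, 200)$p_asymptotic
    if (p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 4)  # <= 10% at this scale; acceptance enforces 6/100
})
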