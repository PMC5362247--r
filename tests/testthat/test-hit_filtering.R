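test_that("hit calling uses inclusive enhancer and strict sensitizer cuts", {
  z <- c(a = 3.0, b = 2.9, c = -2.0, d = -2.01, e = 0)
  h <- call_hits(z, 3.0, -2.0)
  expect_equal(h$enhancers, "a")              # >= 3.0 inclusive
  expect_equal(h$sensitizers, "d")            # < -2.0 strict
  expect_equal(call_hits(numeric(0))$enhancers, character(0))

  # threshold nesting
  set.seed(1)
  z <- setNames(rnorm(200, sd = 2), paste0("p", 1:200))
  expect_true(all(call_hits(z, 3)$enhancers %in% call_hits(z, 2)$enhancers))
})

test_that("counter-screen cutoff is the minimum scrambled-control Z", {
  expect_equal(counterscreen_threshold(c(0.0, -0.2, -0.7)), -0.7)
  expect_equal(counterscreen_threshold(-1.1), -1.1)
  set.seed(2)                              # 16 controls with planted minimum
  ctrl <- c(rnorm(15, 0, 0.2), -0.5)
  expect_equal(counterscreen_threshold(ctrl), -0.5)
  expect_error(counterscreen_threshold(numeric(0)), "nonempty")
})

test_that("counter-screen elimination is inclusive and flags untested pools", {
  counter <- c(RGS3 = -3.09, MYC = -0.29, MAX = -0.93, EDGE = -0.5)
  cs <- apply_counterscreen(c("RGS3", "MYC", "MAX", "EDGE", "NEW"), counter, -0.5)
  expect_true("RGS3" %in% cs$eliminated)
  expect_true("MAX" %in% cs$eliminated)
  expect_true("EDGE" %in% cs$eliminated)   # <= is inclusive
  expect_true("MYC" %in% cs$retained)
  expect_equal(cs$untested, "NEW")         # absent pools retained with flag
  # bookkeeping
  expect_setequal(c(cs$retained, cs$eliminated),
                  c("RGS3", "MYC", "MAX", "EDGE", "NEW"))
})

test_that("expression filter passes if either condition mean exceeds the cut", {
  expr <- structure(data.frame(
    gene = c("RNASEL", "FOSB", "BOUND", "LOW"),
    fpkm_minus_dox = c(0.94, 0.16, 0.5, 0.1),
    fpkm_plus_dox = c(0.54, 8.59, 0.5, 0.2)),
    class = c("expression_table", "data.frame"))
  ef <- apply_expression_filter(c("RNASEL", "FOSB", "BOUND", "LOW", "MISSING"), expr)
  expect_setequal(ef$retained, c("RNASEL", "FOSB"))  # FOSB via +induction arm
  expect_true("BOUND" %in% ef$eliminated)            # strict > at the boundary
  expect_equal(ef$no_data, "MISSING")
  # overall-mean mode: FOSB still passes ((0.16+8.59)/2 > 0.5)
  ef2 <- apply_expression_filter("FOSB", expr, rule = "overall_mean")
  expect_equal(ef2$retained, "FOSB")
  expect_setequal(c(ef$retained, ef$eliminated),
                  c("RNASEL", "FOSB", "BOUND", "LOW", "MISSING"))
})

test_that("cascade verdicts match planted truth on a synthetic screen", {
  sim <- toy_screen(seed = 11, n_genes = 200, prop_rescuer = 0.05,
                    prop_offtarget = 0.02, prop_dox_inhibitor = 0.02)
  sp <- score_bundle(sim$primary)
  sc <- score_bundle(sim$counter)
  counter_z <- setNames(sc$mean_z, sc$pool_id)
  dstat <- local({
    hits <- call_hits(setNames(sp$mean_z, sp$pool_id))$enhancers
    tr <- sim$truth[sim$truth$pool_id %in% hits, ]
    res <- deconvolve_pools(simulate_deconvolution(tr, cv = 0.1, seed = 12))
    setNames(res$classification,
             setNames(sim$truth$gene, sim$truth$pool_id)[res$pool_id])
  })
  rep <- run_cascade(sp, counter = counter_z, expression = sim$expression,
                     control_z = control_scores(sc), deconvolution = dstat)

  g <- rep$genes
  tr <- sim$truth[match(g$gene, sim$truth$gene), ]
  # no null or off-target gene in the final list; expressed rescuers recovered
  expect_true(all(tr$class[g$final_pass] == "true_rescuer"))
  # stage flags: final_pass implies every applied stage passed
  fp <- g[g$final_pass, ]
  expect_true(all(fp$primary_hit & fp$counter_pass & fp$expression_pass))
  # stage counts monotone non-increasing after hit calling
  sc_counts <- rep$stage_counts
  expect_true(all(diff(sc_counts[c("primary_hits", "after_counterscreen")]) <= 0))
  expect_true(all(diff(sc_counts[c("genes_after_counterscreen",
                                   "after_expression", "final")]) <= 0))
  # final list ordered by mean Z descending
  expect_false(is.unsorted(rev(g$primary_z[match(rep$final_genes, g$gene)])))
})

test_that("a gene failing only expression fails only that stage", {
  scores <- data.frame(pool_id = c("P1", "P2"), gene = c("G1", "G2"),
                       mean_z = c(4, 5))
  counter <- c(P1 = 0, P2 = 0.1)
  expr <- structure(data.frame(gene = c("G1", "G2"),
                               fpkm_minus_dox = c(0.1, 5),
                               fpkm_plus_dox = c(0.2, 5)),
                    class = c("expression_table", "data.frame"))
  rep <- run_cascade(scores, counter, expr, counter_cut = -0.5)
  g1 <- rep$genes[rep$genes$gene == "G1", ]
  expect_true(g1$primary_hit && g1$counter_pass)
  expect_false(g1$expression_pass)
  expect_false(g1$final_pass)
  expect_equal(rep$final_genes, "G2")
})

test_that("tightening thresholds never grows any retained set", {
  sim <- toy_screen(seed = 5, n_genes = 150, prop_rescuer = 0.06)
  sp <- score_bundle(sim$primary)
  sc <- score_bundle(sim$counter)
  counter_z <- setNames(sc$mean_z, sc$pool_id)
  prev <- NULL
  for (zmin in c(2, 2.5, 3, 4)) {
    r <- run_cascade(sp, counter_z, sim$expression, z_enhancer = zmin,
                     counter_cut = -0.5)
    if (!is.null(prev)) expect_true(all(r$final_genes %in% prev))
    prev <- r$final_genes
  }
  prev <- NULL
  for (fp in c(0.1, 0.5, 2, 10)) {
    r <- run_cascade(sp, counter_z, sim$expression, counter_cut = -0.5,
                     min_fpkm = fp)
    if (!is.null(prev)) expect_true(all(r$final_genes %in% prev))
    prev <- r$final_genes
  }
})

test_that("counter-screen and expression filters commute as set operations", {
  genes <- paste0("G", 1:20)
  set.seed(9)
  counter <- setNames(rnorm(20), genes)
  expr <- structure(data.frame(gene = genes,
                               fpkm_minus_dox = runif(20, 0, 2),
                               fpkm_plus_dox = runif(20, 0, 2)),
                    class = c("expression_table", "data.frame"))
  a <- apply_expression_filter(
    apply_counterscreen(genes, counter, -0.5)$retained, expr)$retained
  b <- apply_counterscreen(
    apply_expression_filter(genes, expr)$retained, counter, -0.5)$retained
  expect_setequal(a, b)
})

test_that("Spearman correlation matches the rank-formula oracle", {
  x <- c(a = 1, b = 2, c = 3, d = 4)
  y <- c(a = 2, b = 1, c = 4, d = 3)
  r <- screen_correlation(x, y)
  expect_equal(r$rho, 0.6)                         # 1 - 6*4/(4*15)
  expect_equal(r$rho, oracle_spearman_noties(x, y))
  expect_equal(r$n, 4L)

  # strictly monotone transforms leave rho at +/-1
  z <- setNames(runif(10), letters[1:10])
  expect_equal(screen_correlation(z, exp(3 * z))$rho, 1.0)
  expect_equal(screen_correlation(z, -z^3)$rho, -1.0)

  # invariance of rho under monotone transform of either vector; |rho| <= 1
  set.seed(3)
  for (i in 1:20) {
    x <- setNames(rnorm(15), paste0("p", 1:15))
    y <- setNames(rnorm(15), paste0("p", 1:15))
    r0 <- screen_correlation(x, y)$rho
    expect_equal(screen_correlation(exp(x), y)$rho, r0)
    expect_lte(abs(r0), 1)
  }
  expect_error(screen_correlation(c(a = 1, b = 2), c(a = 1, b = 2)),
               "at least 3")
})
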