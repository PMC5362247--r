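test_that("config validation enforces proportions, fractions and the seed", {
  expect_error(sim_config(n_genes = 10), "seed is mandatory")
  expect_error(sim_config(prop_rescuer = 0.8, prop_offtarget = 0.3, seed = 1),
               "sum")
  expect_error(sim_config(kill_fraction = -0.1, seed = 1))
  expect_s3_class(sim_config(seed = 1), "sim_config")
})

test_that("noiseless rescuer ratio is survival over kill exactly", {
  cfg <- sim_config(n_genes = 100, n_replicates = 1, prop_rescuer = 0.01,
                    prop_offtarget = 0, prop_dox_inhibitor = 0,
                    rescue_range = c(0.60, 0.60), kill_fraction = 0.05,
                    well_cv = 0, plate_scale_sd = 0, seed = 33)
  sim <- simulate_screen(cfg)
  lay <- sim$primary$layout
  np <- normalize_plate(sim$primary$measurements,
                        lay[lay$plate_id == "PL01", ])
  ratios <- setNames(unname(np$ratios), np$pools)
  resc <- sim$truth$pool_id[sim$truth$class == "true_rescuer"]
  expect_length(resc, 1L)
  expect_equal(unname(ratios[resc]), 12.0, tolerance = 1e-12)
  # every null pool sits exactly at the plate median (so the Z scale is
  # degenerate here: score_replicate must refuse it rather than divide)
  expect_equal(unname(ratios[names(ratios) != resc]), rep(1, 99),
               tolerance = 1e-12)
  expect_error(score_bundle(sim$primary), "zero dispersion")
})

test_that("same seed gives byte-identical bundles", {
  sim1 <- toy_screen(seed = 99, n_genes = 30)
  sim2 <- toy_screen(seed = 99, n_genes = 30)
  d1 <- tempfile(); d2 <- tempfile()
  write_screen_bundle(sim1$primary, d1)
  write_screen_bundle(sim2$primary, d2)
  for (fn in c("layout.tsv", "measurements.tsv", "library.tsv")) {
    expect_identical(readLines(file.path(d1, fn)), readLines(file.path(d2, fn)))
  }
  expect_identical(sim1$truth, sim2$truth)
  # different seed, different noise
  sim3 <- toy_screen(seed = 100, n_genes = 30)
  expect_false(identical(sim3$primary$measurements$signal,
                         sim1$primary$measurements$signal))
})

test_that("scrambled controls sit at the kill fraction with unit ratio", {
  sim <- toy_screen(seed = 13, n_genes = 352, well_cv = 0.10,
                    plate_scale_sd = 0)
  b <- sim$primary
  lay <- b$layout
  scram <- paste(lay$plate_id, lay$replicate_id, lay$well)[
    lay$role == "scrambled_control"]
  key <- paste(b$measurements$plate_id, b$measurements$replicate_id,
               b$measurements$well)
  sig <- b$measurements$signal[key %in% scram]
  # raw scrambled signal ~ baseline * kill_fraction, within the well CV
  expect_equal(mean(sig) / (1e4 * 0.047), 1, tolerance = 0.05)
  # normalized ratio ~ 1 (scrambled behaves like the null majority)
  s <- score_bundle(b)
  ctrl <- attr(s, "control_ratios")
  expect_equal(mean(ctrl$ratio[ctrl$role == "scrambled_control"]), 1,
               tolerance = 0.05)
})

test_that("simulated deconvolution is exact at cv = 0", {
  tr <- data.frame(pool_id = c("OT", "RES"),
                   class = c("offtarget_single", "true_rescuer"),
                   survival = c(0.4, 0.4), synergy = FALSE)
  attr(tr, "kill_fraction") <- 0.05
  f <- simulate_deconvolution(tr, cv = 0, seed = 2)
  ot <- f[f$pool_id == "OT", ]
  expect_equal(sort(ot$fold_rescue[ot$sirna_id != "POOL3"], decreasing = TRUE),
               c(8, 1, 1, 1))
  expect_equal(ot$fold_rescue[ot$sirna_id == "POOL3"], 1.0)
  res <- deconvolve_pools(f)
  cls <- setNames(res$classification, res$pool_id)
  expect_equal(unname(cls["OT"]), "single_dominant")
  expect_equal(unname(cls["RES"]), "on_target_multi")
})

test_that("simulated time courses obey the stated decay law", {
  tc <- simulate_timecourse(60, times = c(0, 60, 120), cv = 0, seed = 1)
  expect_equal(tc$abundance, c(1, 0.5, 0.25), tolerance = 1e-12)
  flat <- simulate_timecourse(Inf, times = c(0, 60, 120), cv = 0, seed = 1)
  expect_equal(flat$abundance, rep(1, 3))
  expect_error(simulate_timecourse(-5, seed = 1), "> 0")
  expect_error(simulate_timecourse(60), "seed")
  # noisy recovery within 10%
  tc <- simulate_timecourse(44, cv = 0.05, seed = 3)
  expect_equal(fit_decay(tc)$half_life, 44, tolerance = 0.10)
})

test_that("recovery metrics match a brute-force confusion tally", {
  # perfect verdicts
  tr <- data.frame(gene = c("A", "B", "C"), pool_id = c("pA", "pB", "pC"),
                   class = c("true_rescuer", "null", "null"))
  rep_perfect <- structure(list(genes = data.frame(
    gene = c("A", "B", "C"), final_pass = c(TRUE, FALSE, FALSE))),
    class = "cascade_report")
  ev <- evaluate_recovery(rep_perfect, tr)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$fdr, 0.0)

  # zero positives called -> sensitivity 0, FDR 0 by convention
  rep_none <- structure(list(genes = data.frame(
    gene = c("A", "B", "C"), final_pass = c(FALSE, FALSE, FALSE))),
    class = "cascade_report")
  ev0 <- evaluate_recovery(rep_none, tr)
  expect_equal(ev0$sensitivity, 0.0)
  expect_equal(ev0$fdr, 0.0)

  # random small case vs exhaustive tally
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    cls <- sample(c("true_rescuer", "null", "offtarget_single"), n, replace = TRUE)
    called <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tr <- data.frame(gene = paste0("g", 1:n), pool_id = paste0("p", 1:n),
                     class = cls)
    rp <- structure(list(genes = data.frame(gene = tr$gene, final_pass = called)),
                    class = "cascade_report")
    ev <- evaluate_recovery(rp, tr)
    oc <- oracle_confusion(cls, called)
    expect_equal(sum(ev$confusion), n)
    for (cl in names(oc)) {
      expect_equal(unname(ev$confusion[cl, "positive"]), unname(oc[[cl]]["positive"]))
    }
    tp <- sum(called & cls == "true_rescuer")
    fp <- sum(called & cls != "true_rescuer")
    if (tp + fp > 0) expect_equal(ev$fdr, fp / (tp + fp))
  }

  # identifier mismatch is an error
  bad <- data.frame(gene = "ZZZ", pool_id = "pZ", class = "null")
  expect_error(evaluate_recovery(rep_perfect, bad), "absent")
})

test_that("planted low-expression genes always fail the expression stage", {
  sim <- toy_screen(seed = 19, n_genes = 200, low_expression_fraction = 0.2)
  low <- sim$truth$gene[sim$truth$low_expression]
  ef <- apply_expression_filter(low, sim$expression)
  expect_length(ef$retained, 0L)          # expression is noiseless: rate 1.0
})
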