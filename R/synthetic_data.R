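# Synthetic screens with known ground truth.  The generator emulates the
# statistical structure of an inducible-lethality rescue screen: a lethal
# induction drops sample-well viability to a few percent of the uninduced
# baseline, planted rescuer pools restore 30-75% viability, off-target pools
# carry a single dominant rescuing siRNA, induction-inhibitor pools also
# score in the reporter counter-screen, plates have lognormal scale factors,
# and wells have multiplicative lognormal noise.

#' Simulation configuration
#'
#' Defaults state the emulated screen: 384-well plates with 352 sample
#' wells, 16 scrambled controls and 4 positive-control wells each; lethal
#' induction leaving non-rescued wells at 4.7% of the uninduced signal;
#' planted rescuers restoring 30-75% viability; 10% well CV.  Class
#' proportions must leave a non-negative null remainder.
#'
#' @param n_genes number of library genes (one pool each).
#' @param n_replicates replicate plate sets (default 3).
#' @param prop_rescuer,prop_offtarget,prop_dox_inhibitor planted class
#'   proportions (defaults 0.02 / 0.01 / 0.01; remainder is null).
#' @param kill_fraction induced viability of non-rescued wells as a fraction
#'   of the uninduced baseline (default 0.047, the scrambled-control level).
#' @param rescue_range survival fraction range for planted rescuers
#'   (default `c(0.30, 0.75)`).
#' @param low_expression_fraction fraction of genes with FPKM < 0.5 in both
#'   conditions (default 0.10); drawn from non-rescuer classes, since a gene
#'   that is not expressed cannot mediate an on-target rescue.
#' @param plate_scale_sd sdlog of the lognormal per-plate scale factor
#'   (default 0.10).
#' @param well_cv multiplicative well noise CV (default 0.10).
#' @param baseline_rlu uninduced signal level (default 1e4 relative light
#'   units).
#' @param pos_control_survival viability of the positive-control knockdown
#'   (default 1.0 — full rescue; survival cannot exceed the uninduced
#'   baseline).
#' @param counter_inhibition_range reporter signal fraction for planted
#'   induction inhibitors in the counter-screen (default `c(0.1, 0.5)`).
#' @param synergy_fraction fraction of rescuers whose pool effect comes from
#'   synergy of individually weak siRNAs (default 0.1).
#' @param seed integer RNG seed; mandatory.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000, n_replicates = 3,
                       prop_rescuer = 0.02, prop_offtarget = 0.01,
                       prop_dox_inhibitor = 0.01,
                       kill_fraction = 0.047,
                       rescue_range = c(0.30, 0.75),
                       low_expression_fraction = 0.10,
                       plate_scale_sd = 0.10, well_cv = 0.10,
                       baseline_rlu = 1e4, pos_control_survival = 1.0,
                       counter_inhibition_range = c(0.1, 0.5),
                       synergy_fraction = 0.1,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  props <- c(prop_rescuer, prop_offtarget, prop_dox_inhibitor)
  if (any(props < 0) || sum(props) > 1) {
    stop("class proportions must be >= 0 and sum to <= 1", call. = FALSE)
  }
  fr <- c(kill_fraction, low_expression_fraction, synergy_fraction,
          rescue_range, pos_control_survival)
  if (any(fr < 0) || any(fr > 1)) {
    stopifnot(all(fr >= 0), all(fr <= 1))
  }
  stopifnot(n_genes >= 1, n_replicates >= 1, well_cv >= 0, plate_scale_sd >= 0,
            kill_fraction > 0, baseline_rlu > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 prop_rescuer = prop_rescuer, prop_offtarget = prop_offtarget,
                 prop_dox_inhibitor = prop_dox_inhibitor,
                 kill_fraction = kill_fraction, rescue_range = rescue_range,
                 low_expression_fraction = low_expression_fraction,
                 plate_scale_sd = plate_scale_sd, well_cv = well_cv,
                 baseline_rlu = baseline_rlu,
                 pos_control_survival = pos_control_survival,
                 counter_inhibition_range = counter_inhibition_range,
                 synergy_fraction = synergy_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

lognoise <- function(n, cv) {
  if (cv == 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = cv_to_sdlog(cv))
}

# 384-well plate template: columns 1-22 sample slots (row-major), column 23
# scrambled controls, column 24 rows A-D positive controls, rest empty.
plate_template <- function() {
  rows <- LETTERS[1:16]
  sample_wells <- as.vector(t(outer(rows, 1:22, paste0)))
  scram <- paste0(rows, 23)
  pos <- paste0(rows[1:4], 24)
  empty <- paste0(rows[5:16], 24)
  list(sample = sample_wells, scrambled = scram, pos = pos, empty = empty)
}

#' Simulate a rescue screen with its counter-screen
#'
#' Generates a primary (lethal-induction) screen bundle, a reporter
#' counter-screen bundle on the same plate set, a noiseless expression
#' table, and the ground truth.  Sample-well signal is
#' `baseline x plate_factor x viability(class) x lognormal(cv)`; the
#' counter-screen reporter is depressed only for the induction-inhibitor
#' class.  One plate set is shared across replicates (a replicate is a
#' re-measured plate with fresh noise).  Fully deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a `sim_screen` list: `primary` and `counter` (`screen_bundle`s),
#'   `expression` (`expression_table`), `truth` (`sim_truth` data frame) and
#'   `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_genes

  wd <- max(4L, nchar(as.character(n)))
  gene <- sprintf("GENE%0*d", wd, seq_len(n))
  pool <- sprintf("POOL%0*d", wd, seq_len(n))

  n_res <- round(n * config$prop_rescuer)
  n_off <- round(n * config$prop_offtarget)
  n_dox <- round(n * config$prop_dox_inhibitor)
  cls <- rep("null", n)
  planted <- sample.int(n, n_res + n_off + n_dox)
  cls[planted[seq_len(n_res)]] <- "true_rescuer"
  if (n_off > 0) cls[planted[n_res + seq_len(n_off)]] <- "offtarget_single"
  if (n_dox > 0) cls[planted[n_res + n_off + seq_len(n_dox)]] <- "dox_inhibitor"

  survival <- rep(config$kill_fraction, n)
  rescued <- cls != "null"
  survival[rescued] <- stats::runif(sum(rescued), config$rescue_range[1L],
                                    config$rescue_range[2L])
  synergy <- cls == "true_rescuer" &
    stats::runif(n) < config$synergy_fraction

  # expression: rescuers are always expressed; low-expression genes come
  # from the other classes.  Noiseless (single value per gene).
  fpkm_lo <- exp(stats::rnorm(n, log(8), 1))
  fpkm_hi <- exp(stats::rnorm(n, log(8), 1))
  fpkm_lo <- pmax(fpkm_lo, 0.6)
  fpkm_hi <- pmax(fpkm_hi, 0.6)
  n_low <- round(n * config$low_expression_fraction)
  eligible <- which(cls != "true_rescuer")
  low <- sample(eligible, min(n_low, length(eligible)))
  fpkm_lo[low] <- stats::runif(length(low), 0.01, 0.45)
  fpkm_hi[low] <- stats::runif(length(low), 0.01, 0.45)

  expression <- structure(
    data.frame(gene = gene, fpkm_minus_dox = round(fpkm_lo, 3),
               fpkm_plus_dox = round(fpkm_hi, 3), stringsAsFactors = FALSE),
    class = c("expression_table", "data.frame"))

  truth <- structure(
    data.frame(gene = gene, pool_id = pool, class = cls,
               survival = survival, synergy = synergy,
               low_expression = seq_len(n) %in% low,
               fpkm_minus_dox = expression$fpkm_minus_dox,
               fpkm_plus_dox = expression$fpkm_plus_dox,
               stringsAsFactors = FALSE),
    kill_fraction = config$kill_fraction,
    class = c("sim_truth", "data.frame"))

  # library: four siRNAs per pool
  lib <- structure(
    data.frame(pool_id = rep(pool, each = 4L),
               gene = rep(gene, each = 4L),
               sirna_id = paste0(rep(pool, each = 4L), "_s", 1:4),
               isoform_note = NA_character_, stringsAsFactors = FALSE),
    class = c("sirna_library", "data.frame"))

  # layout: shared plate set across replicates
  tmpl <- plate_template()
  per_plate <- length(tmpl$sample)
  n_plates <- ceiling(n / per_plate)
  lay1 <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, n)
    k <- length(idx)
    data.frame(
      plate_id = sprintf("PL%02d", p),
      well = canonical_well(c(tmpl$sample[seq_len(k)], tmpl$scrambled,
                              tmpl$pos, tmpl$empty)),
      role = c(rep("sample", k), rep("scrambled_control", 16L),
               rep("pos_control", 4L), rep("empty", 12L)),
      content_id = c(pool[idx], sprintf("SCRAMBLED_%02d", 1:16),
                     sprintf("POSCTRL_%d", 1:4), rep(NA_character_, 12L)),
      viability = c(survival[idx], rep(config$kill_fraction, 16L),
                    rep(config$pos_control_survival, 4L), rep(0.002, 12L)),
      luc_factor = c(ifelse(cls[idx] == "dox_inhibitor", NA, 1)[seq_len(k)],
                     rep(1, 32L)),
      stringsAsFactors = FALSE)
  }))
  # counter-screen inhibition factor for planted dox inhibitors
  dox_idx <- is.na(lay1$luc_factor)
  lay1$luc_factor[dox_idx] <- stats::runif(sum(dox_idx),
                                           config$counter_inhibition_range[1L],
                                           config$counter_inhibition_range[2L])

  reps <- sprintf("R%d", seq_len(config$n_replicates))
  layout <- do.call(rbind, lapply(reps, function(r) {
    cbind(lay1[c("plate_id", "well", "role", "content_id")],
          replicate_id = r, stringsAsFactors = FALSE)
  }))
  layout <- layout[c("plate_id", "replicate_id", "well", "role", "content_id")]
  class(layout) <- c("screen_layout", "data.frame")

  measure <- function(per_well_factor) {
    do.call(rbind, lapply(reps, function(r) {
      do.call(rbind, lapply(unique(lay1$plate_id), function(p) {
        rowsel <- lay1$plate_id == p
        pf <- if (config$plate_scale_sd == 0) 1 else
          stats::rlnorm(1L, 0, config$plate_scale_sd)
        sig <- config$baseline_rlu * pf * per_well_factor[rowsel] *
          lognoise(sum(rowsel), config$well_cv)
        data.frame(plate_id = p, replicate_id = r, well = lay1$well[rowsel],
                   signal = sig, stringsAsFactors = FALSE)
      }))
    }))
  }
  meas_primary <- measure(lay1$viability)
  meas_counter <- measure(lay1$luc_factor)
  class(meas_primary) <- class(meas_counter) <- c("measurement_set", "data.frame")

  bundle <- function(m) structure(list(layout = layout, measurements = m,
                                       library = lib), class = "screen_bundle")
  structure(list(primary = bundle(meas_primary),
                 counter = bundle(meas_counter),
                 expression = expression, truth = truth, config = config),
            class = "sim_screen")
}

#' Simulate a pool-deconvolution experiment
#'
#' For each pool in `truth`, draws per-siRNA fold rescues (relative to the
#' non-silencing control under induction) plus a triple-pool measurement of
#' the three weakest siRNAs, following the planted class: rescuers have >= 2
#' siRNAs near the pool effect (or, for synergy-type rescuers, one strong
#' siRNA with a rescuing triple pool); off-target and induction-inhibitor
#' pools have exactly one strong siRNA and an inert triple pool; null pools
#' rescue nowhere.
#'
#' @param truth a `sim_truth` data frame (or subset of its rows).
#' @param cv multiplicative noise CV (default 0.15).
#' @param seed integer RNG seed.
#' @return data frame with columns `pool_id`, `sirna_id`, `fold_rescue`;
#'   triple-pool rows have `sirna_id == "POOL3"`.
#' @export
simulate_deconvolution <- function(truth, cv = 0.15, seed) {
  stopifnot(is.data.frame(truth),
            all(c("pool_id", "class", "survival") %in% names(truth)))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")

  kill <- if (!is.null(attr(truth, "kill_fraction"))) {
    attr(truth, "kill_fraction")
  } else 0.047
  out <- lapply(seq_len(nrow(truth)), function(i) {
    cls <- truth$class[i]
    effect <- truth$survival[i] / kill      # fold over the scrambled control
    syn <- isTRUE(truth$synergy[i])
    # inert siRNAs sit at fold 1 before noise; synergy-type rescuers have
    # mildly active but individually non-rescuing partners
    folds <- switch(cls,
      true_rescuer = if (syn) c(effect, rep(1.2, 3)) else c(rep(effect, 3), 1),
      offtarget_single = c(effect, rep(1, 3)),
      dox_inhibitor = c(effect, rep(1, 3)),
      rep(1, 4))
    triple <- if (cls == "true_rescuer") effect else 1
    f <- c(folds, triple) * lognoise(5L, cv)
    data.frame(pool_id = truth$pool_id[i],
               sirna_id = c(paste0(truth$pool_id[i], "_s", 1:4), "POOL3"),
               fold_rescue = f, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Simulate a shutoff decay time course
#'
#' Abundance follows `exp(-ln(2) t / t_half)` with multiplicative lognormal
#' noise; the t = 0 point is included and the series renormalized to it.
#' `half_life_min = Inf` gives a non-decaying (flat) series.
#'
#' @param half_life_min true half-life in minutes (> 0, or `Inf`).
#' @param times sampling times in minutes (default 7 points over 0-120).
#' @param cv multiplicative noise CV (default 0.05).
#' @param seed integer RNG seed.
#' @return a `decay_timecourse`.
#' @export
simulate_timecourse <- function(half_life_min,
                                times = c(0, 10, 20, 40, 60, 90, 120),
                                cv = 0.05, seed) {
  if (!is.infinite(half_life_min) && half_life_min <= 0) {
    stop("half_life_min must be > 0 (or Inf for non-decaying)", call. = FALSE)
  }
  stopifnot(!is.unsorted(times, strictly = TRUE), cv >= 0)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  mu <- if (is.infinite(half_life_min)) rep(1, length(times)) else
    exp(-log(2) * times / half_life_min)
  decay_timecourse(times, mu * lognoise(length(times), cv),
                   label = sprintf("sim t1/2 = %s min", format(half_life_min)))
}

#' Evaluate pipeline recovery against planted truth
#'
#' For a `cascade_report`, positives are genes with `final_pass`; for a
#' `deconvolution_result`, positives are pools classified on-target.
#' Sensitivity is TP/(TP+FN) over the `true_rescuer` class; FDR is
#' FP/(TP+FP), defined as 0 when nothing is called positive.  Confusion
#' counts are per planted class and sum to the number of genes evaluated.
#'
#' @param report a `cascade_report` or `deconvolution_result`.
#' @param truth a `sim_truth` data frame covering the same identifiers.
#' @return list with `sensitivity`, `fdr`, `confusion` (class x called
#'   table) and, for deconvolution input, `accuracy`.
#' @export
evaluate_recovery <- function(report, truth) {
  stopifnot(is.data.frame(truth))
  if (inherits(report, "cascade_report")) {
    g <- report$genes
    if (!all(truth$gene %in% g$gene)) {
      stop("truth contains genes absent from the cascade report", call. = FALSE)
    }
    called_pos <- truth$gene %in% g$gene[g$final_pass]
    accuracy <- NULL
  } else if (inherits(report, "deconvolution_result") ||
             (is.data.frame(report) && "classification" %in% names(report))) {
    if (!all(truth$pool_id %in% report$pool_id)) {
      stop("truth contains pools absent from the deconvolution result", call. = FALSE)
    }
    cls <- stats::setNames(report$classification, report$pool_id)[truth$pool_id]
    called_pos <- cls %in% c("on_target_multi", "on_target_synergy")
    expected <- ifelse(truth$class == "true_rescuer", "on_target",
                       ifelse(truth$class == "null", "no_rescue", "single_dominant"))
    observed <- ifelse(cls %in% c("on_target_multi", "on_target_synergy"),
                       "on_target", cls)
    accuracy <- mean(observed == expected)
  } else {
    stop("report must be a cascade_report or deconvolution result", call. = FALSE)
  }
  is_pos <- truth$class == "true_rescuer"
  tp <- sum(called_pos & is_pos)
  fp <- sum(called_pos & !is_pos)
  fn <- sum(!called_pos & is_pos)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  confusion <- table(class = truth$class,
                     called = factor(ifelse(called_pos, "positive", "negative"),
                                     levels = c("positive", "negative")))
  out <- list(sensitivity = sens, fdr = fdr, confusion = confusion)
  if (!is.null(accuracy)) out$accuracy <- accuracy
  out
}
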