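# Hit filtering: threshold hit calling, counter-screen elimination,
# expression filtering, the reported cascade, and screen-correlation
# diagnostics.

#' Call enhancer and sensitizer hits from mean Z-scores
#'
#' Enhancers increase viability under the lethal induction (Z >= the
#' enhancer threshold, inclusive); sensitizers decrease it (Z strictly below
#' the sensitizer threshold).
#'
#' @param scores named numeric vector, pool -> mean Z.
#' @param z_enhancer enhancer threshold (default 3.0).
#' @param z_sensitizer sensitizer threshold (default -2.0).
#' @return list with character vectors `enhancers` and `sensitizers`.
#' @export
call_hits <- function(scores, z_enhancer = 3.0, z_sensitizer = -2.0) {
  stopifnot(is.finite(z_enhancer), is.finite(z_sensitizer),
            z_enhancer > z_sensitizer)
  z <- scores[!is.na(scores)]
  nm <- if (is.null(names(z))) character(length(z)) else names(z)
  list(enhancers = nm[z >= z_enhancer],
       sensitizers = nm[z < z_sensitizer])
}

#' Derive the counter-screen cutoff from scrambled controls
#'
#' The elimination cutoff is the minimum Z-score observed among the
#' scrambled (non-silencing) control siRNAs of the counter-screen: any pool
#' depressing the reporter more than every control is suspect.
#'
#' @param control_z numeric vector of scrambled-control Z-scores (nonempty).
#' @return the minimum control Z.
#' @export
counterscreen_threshold <- function(control_z) {
  if (length(control_z) == 0L || anyNA(control_z)) {
    stop("counter-screen cutoff needs a nonempty control Z list ",
         "(or pass a manual threshold)", call. = FALSE)
  }
  min(control_z)
}

#' Eliminate candidates that suppress reporter induction
#'
#' A candidate is eliminated when its counter-screen Z is less than or equal
#' to the threshold (inclusive).  Candidates absent from the counter table
#' are retained and flagged `"untested"`.
#'
#' @param candidates character vector of pool ids.
#' @param counter named numeric vector, pool -> counter-screen mean Z.
#' @param threshold elimination cutoff (e.g. from
#'   [counterscreen_threshold()]).
#' @return list with `retained`, `eliminated` and `untested` (subset of
#'   retained) character vectors.
#' @export
apply_counterscreen <- function(candidates, counter, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  cz <- counter[candidates]
  eliminated <- candidates[!is.na(cz) & cz <= threshold]
  retained <- setdiff(candidates, eliminated)
  list(retained = retained, eliminated = eliminated,
       untested = candidates[is.na(cz)])
}

#' Filter genes on expression level
#'
#' A gene passes when it is expressed above `min_fpkm` (strictly).  Under the
#' default `"either"` rule the larger of the two condition means must exceed
#' the cutoff — a gene strongly induced by the stimulus counts as expressed
#' even if silent at baseline.  Under `"overall_mean"` the mean of the two
#' conditions is compared instead.  Genes absent from the table fail and are
#' flagged.
#'
#' @param genes character vector of gene symbols.
#' @param expression an `expression_table`.
#' @param min_fpkm expression cutoff (default 0.5).
#' @param rule `"either"` (default) or `"overall_mean"`.
#' @return list with `retained`, `eliminated` and `no_data` (subset of
#'   eliminated) character vectors.
#' @export
apply_expression_filter <- function(genes, expression, min_fpkm = 0.5,
                                    rule = c("either", "overall_mean")) {
  rule <- match.arg(rule)
  stopifnot(min_fpkm >= 0)
  idx <- match(genes, expression$gene)
  lo <- expression$fpkm_minus_dox[idx]
  hi <- expression$fpkm_plus_dox[idx]
  stat <- if (rule == "either") pmax(lo, hi) else (lo + hi) / 2
  pass <- !is.na(stat) & stat > min_fpkm
  list(retained = genes[pass], eliminated = genes[!pass],
       no_data = genes[is.na(idx)])
}

#' Run the full hit-filter cascade
#'
#' Applies, in order: enhancer hit calling on the primary mean Z; the
#' counter-screen filter at pool level; collapse to gene level (best pool per
#' gene by mean Z); the expression filter; and, when supplied, the pool
#' deconvolution verdict (only `on_target_multi` / `on_target_synergy`
#' pass; genes without a deconvolution result are retained and flagged).
#' The final gene list is ordered by mean Z, descending.
#'
#' @param scores a `gene_score` data frame (from [summarize_scores()] /
#'   [score_bundle()]) or a named pool -> mean Z vector plus `gene_map`.
#' @param counter named pool -> counter Z vector, or `NULL` to skip the stage.
#' @param expression an `expression_table`, or `NULL` to skip the stage.
#' @param z_enhancer primary hit threshold (default 3.0).
#' @param counter_cut numeric cutoff, or `"auto"` to derive it from
#'   `control_z` via [counterscreen_threshold()].
#' @param control_z scrambled-control Z values (needed when
#'   `counter_cut = "auto"`).
#' @param min_fpkm expression cutoff (default 0.5).
#' @param expression_rule see [apply_expression_filter()].
#' @param deconvolution optional named character vector, gene ->
#'   classification from [classify_deconvolution()] / [classify_synergy()].
#' @param gene_map named pool -> gene vector when `scores` is a bare vector.
#' @return a `cascade_report` list: `genes` (per-gene data frame),
#'   `stage_counts`, `final_genes`, `thresholds`.
#' @export
run_cascade <- function(scores, counter = NULL, expression = NULL,
                        z_enhancer = 3.0, counter_cut = "auto",
                        control_z = NULL, min_fpkm = 0.5,
                        expression_rule = "either",
                        deconvolution = NULL, gene_map = NULL) {
  if (inherits(scores, "gene_score") || is.data.frame(scores)) {
    pool_z <- stats::setNames(scores$mean_z, scores$pool_id)
    gene_map <- stats::setNames(scores$gene, scores$pool_id)
  } else {
    pool_z <- scores
    if (is.null(gene_map)) gene_map <- stats::setNames(names(pool_z), names(pool_z))
  }

  hits <- call_hits(pool_z, z_enhancer = z_enhancer)
  primary_pools <- hits$enhancers

  if (!is.null(counter)) {
    if (identical(counter_cut, "auto")) counter_cut <- counterscreen_threshold(control_z)
    cs <- apply_counterscreen(primary_pools, counter, counter_cut)
    counter_pools <- cs$retained
  } else {
    counter_cut <- NA_real_
    cs <- list(retained = primary_pools, eliminated = character(0),
               untested = primary_pools)
    counter_pools <- primary_pools
  }

  # collapse to gene level: best surviving pool per gene
  surv_gene <- gene_map[counter_pools]
  best_pool <- vapply(split(counter_pools, surv_gene),
                      function(p) p[which.max(pool_z[p])], "")
  genes <- names(best_pool)

  if (!is.null(expression)) {
    ef <- apply_expression_filter(genes, expression, min_fpkm = min_fpkm,
                                  rule = expression_rule)
  } else {
    ef <- list(retained = genes, eliminated = character(0), no_data = character(0))
  }

  if (!is.null(deconvolution)) {
    dstat <- deconvolution[ef$retained]
    dpass <- is.na(dstat) | dstat %in% c("on_target_multi", "on_target_synergy")
    final <- ef$retained[dpass]
  } else {
    dstat <- rep(NA_character_, length(ef$retained))
    final <- ef$retained
  }
  final <- final[order(-pool_z[best_pool[final]])]

  gene_all <- unique(gene_map[names(pool_z)])
  gp <- vapply(split(names(pool_z), gene_map[names(pool_z)]),
               function(p) p[which.max(pool_z[p])], "")[gene_all]
  tab <- data.frame(
    gene = gene_all,
    pool_id = unname(gp),
    primary_z = unname(pool_z[gp]),
    primary_hit = gene_all %in% gene_map[primary_pools],
    counter_z = if (!is.null(counter)) unname(counter[gp]) else NA_real_,
    counter_pass = gene_all %in% gene_map[counter_pools] |
      !(gene_all %in% gene_map[primary_pools]),
    expression_pass = gene_all %in% ef$retained,
    deconvolution_status = if (!is.null(deconvolution))
      unname(deconvolution[gene_all]) else NA_character_,
    final_pass = gene_all %in% final,
    stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(gene_all, expression$gene)
  if (!is.null(expression)) {
    tab$fpkm_minus_dox <- expression$fpkm_minus_dox[idx]
    tab$fpkm_plus_dox <- expression$fpkm_plus_dox[idx]
  }

  structure(list(
    genes = tab,
    stage_counts = c(pools_scored = length(pool_z),
                     primary_hits = length(primary_pools),
                     after_counterscreen = length(counter_pools),
                     genes_after_counterscreen = length(genes),
                     after_expression = length(ef$retained),
                     final = length(final)),
    counter_eliminated = cs$eliminated,
    counter_untested = cs$untested,
    expression_no_data = ef$no_data,
    final_genes = final,
    thresholds = list(z_enhancer = z_enhancer, counter_cut = counter_cut,
                      min_fpkm = min_fpkm, expression_rule = expression_rule)),
    class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Hit-filter cascade\n")
  cat(sprintf("  enhancer Z >= %.2f, counter Z <= %s, FPKM > %.2f (%s)\n",
              x$thresholds$z_enhancer,
              format(x$thresholds$counter_cut, digits = 3),
              x$thresholds$min_fpkm, x$thresholds$expression_rule))
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-26s %d\n", nm, x$stage_counts[[nm]]))
  }
  cat("  final genes:", paste(x$final_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Spearman correlation between two screens
#'
#' Rank correlation (average ranks for ties) over the pools present in both
#' score maps; used as a diagnostic for systematic coupling between a
#' primary screen and its reporter counter-screen.
#'
#' @param primary,counter named numeric vectors, pool -> Z.
#' @return list with `rho` and `n` (shared pools used).
#' @export
screen_correlation <- function(primary, counter) {
  shared <- intersect(names(primary), names(counter))
  x <- primary[shared]
  y <- counter[shared]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    stop("need at least 3 shared pools for a rank correlation", call. = FALSE)
  }
  list(rho = stats::cor(x[ok], y[ok], method = "spearman"), n = sum(ok))
}
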