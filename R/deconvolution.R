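# Pool deconvolution: is a pool's rescue driven by several of its siRNAs
# (on-target) or by a single one (likely off-target)?  Pools with exactly one
# rescuing siRNA get a second chance via the synergy test: the remaining,
# individually non-rescuing siRNAs are re-transfected as a pool of three.

DECONV_CLASSES <- c("no_rescue", "single_dominant", "on_target_synergy",
                    "on_target_multi")

#' Fold rescue relative to a non-silencing control
#'
#' Viability measurements under the lethal induction are expressed as a fold
#' change over the matched non-silencing (scrambled) control, the comparator
#' used for all deconvolution calls.
#'
#' @param viability numeric vector of raw viability signals.
#' @param control viability of the non-silencing control (> 0).
#' @return numeric vector of fold rescues.
#' @export
fold_rescue <- function(viability, control) {
  stopifnot(is.numeric(control), length(control) == 1L, control > 0)
  viability / control
}

#' Classify a deconvoluted siRNA pool
#'
#' Counts the individual siRNAs whose fold rescue reaches `rescue_fold`
#' (inclusive, "2-fold or greater").  Two or more rescuing siRNAs indicate an
#' on-target pool; exactly one is a single-dominant (off-target suspect)
#' pending the synergy test; none is no rescue.  The call is invariant to
#' the order of the fold values.
#'
#' @param fold_rescues numeric vector of per-siRNA fold rescues (length >= 2,
#'   finite, >= 0).
#' @param rescue_fold rescue threshold (default 2.0).
#' @return one of `"on_target_multi"`, `"single_dominant"`, `"no_rescue"`.
#' @export
classify_deconvolution <- function(fold_rescues, rescue_fold = 2.0) {
  x <- as.numeric(fold_rescues)
  if (length(x) < 2L) stop("deconvolution needs >= 2 per-siRNA folds", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("fold rescues must be finite and >= 0", call. = FALSE)
  }
  n <- sum(x >= rescue_fold)
  if (n >= 2L) "on_target_multi" else if (n == 1L) "single_dominant" else "no_rescue"
}

#' Resolve a single-dominant pool with the synergy test
#'
#' For a pool whose rescue was dominated by one siRNA, the three individually
#' non-rescuing siRNAs are pooled and retested: if that triple pool rescues
#' (fold >= `rescue_fold`, inclusive) the original call is upgraded to
#' on-target synergy; otherwise the pool stays single-dominant, i.e. an
#' off-target suspect.
#'
#' @param prior classification from [classify_deconvolution()]; must be
#'   `"single_dominant"`.
#' @param triple_pool_fold fold rescue of the pool of three non-rescuing
#'   siRNAs.
#' @param rescue_fold rescue threshold (default 2.0).
#' @return `"on_target_synergy"` or `"single_dominant"`.
#' @export
classify_synergy <- function(prior, triple_pool_fold, rescue_fold = 2.0) {
  if (!identical(prior, "single_dominant")) {
    stop("synergy test only applies to single_dominant pools, got '",
         prior, "'", call. = FALSE)
  }
  stopifnot(is.numeric(triple_pool_fold), length(triple_pool_fold) == 1L,
            is.finite(triple_pool_fold), triple_pool_fold >= 0)
  if (triple_pool_fold >= rescue_fold) "on_target_synergy" else "single_dominant"
}

#' Deconvolve a table of per-siRNA fold rescues
#'
#' Applies [classify_deconvolution()] pool by pool, and
#' [classify_synergy()] where a triple-pool measurement (rows with
#' `sirna_id == "POOL3"`) is available for a single-dominant pool.
#'
#' @param folds data frame with columns `pool_id`, `sirna_id`,
#'   `fold_rescue`; rows with `sirna_id == "POOL3"` carry the triple-pool
#'   measurement.
#' @param rescue_fold rescue threshold (default 2.0).
#' @return a `deconvolution_result` data frame: `pool_id`, `n_sirna`,
#'   `n_rescuing`, `max_fold`, `synergy_fold`, `classification`.
#' @export
deconvolve_pools <- function(folds, rescue_fold = 2.0) {
  stopifnot(all(c("pool_id", "sirna_id", "fold_rescue") %in% names(folds)))
  out <- lapply(split(folds, folds$pool_id), function(df) {
    singles <- df$fold_rescue[df$sirna_id != "POOL3"]
    triple <- df$fold_rescue[df$sirna_id == "POOL3"]
    cls <- classify_deconvolution(singles, rescue_fold)
    syn <- if (length(triple) >= 1L) triple[1L] else NA_real_
    if (cls == "single_dominant" && !is.na(syn)) {
      cls <- classify_synergy(cls, syn, rescue_fold)
    }
    data.frame(pool_id = df$pool_id[1L], n_sirna = length(singles),
               n_rescuing = sum(singles >= rescue_fold),
               max_fold = max(singles), synergy_fold = syn,
               classification = cls, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  class(res) <- c("deconvolution_result", "data.frame")
  res
}
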