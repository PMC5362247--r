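# Scoring: per-plate median normalization of sample wells, experiment-wide
# robust Z per replicate, and triplicate summarization.

#' Normalize one plate by its sample-well median
#'
#' Divides every sample-well signal by the median of the sample-well signals
#' on that plate (the "median method"), making plates with different overall
#' scales comparable.  Control wells are reported separately and never enter
#' the median.  An additive mode (signal minus plate median) is available for
#' sensitivity analysis; it is not scale-invariant.
#'
#' @param measurements a `measurement_set` (or plain data frame) restricted
#'   to one plate and replicate, or a full set from which the plate named by
#'   the layout is extracted.
#' @param layout a `screen_layout` restricted to the same plate/replicate.
#' @param mode `"multiplicative"` (ratio to plate sample median, default) or
#'   `"additive"` (difference from it).
#' @return a `normalized_plate` list: `plate_id`, `replicate_id`, `mode`,
#'   `ratios` (named by well, sample wells only), `pools` (well -> pool id),
#'   `control_ratios` (named by well) and `control_roles`.
#' @export
normalize_plate <- function(measurements, layout,
                            mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  plate <- unique(layout$plate_id)
  rep_id <- unique(layout$replicate_id)
  if (length(plate) != 1L || length(rep_id) != 1L) {
    stop("normalize_plate() expects exactly one plate and replicate", call. = FALSE)
  }
  m <- measurements[measurements$plate_id == plate &
                      measurements$replicate_id == rep_id, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements for plate ", plate, call. = FALSE)
  sig <- stats::setNames(m$signal, m$well)
  role <- stats::setNames(layout$role, layout$well)[names(sig)]
  if (anyNA(role)) stop("measurement well missing from layout on plate ", plate, call. = FALSE)

  sample_sig <- sig[role == "sample"]
  if (length(sample_sig) == 0L) stop("plate ", plate, " has no sample wells", call. = FALSE)
  med <- stats::median(sample_sig)
  if (mode == "multiplicative" && med <= 0) {
    stop("degenerate plate ", plate, ": sample-well median is ", med, call. = FALSE)
  }
  norm <- if (mode == "multiplicative") function(x) x / med else function(x) x - med
  ctrl <- sig[role != "sample" & role != "empty"]
  structure(list(plate_id = plate, replicate_id = rep_id, mode = mode,
                 sample_median = med,
                 ratios = norm(sample_sig),
                 pools = stats::setNames(layout$content_id, layout$well)[names(sample_sig)],
                 control_ratios = norm(ctrl),
                 control_roles = role[names(ctrl)],
                 control_content = stats::setNames(layout$content_id,
                                                   layout$well)[names(ctrl)]),
            class = "normalized_plate")
}

#' Robust Z-scores for one replicate
#'
#' Z_i = (x_i - median(x)) / (1.4826 * MAD(x)), with the MAD taken as the
#' raw median absolute deviation and 1.4826 the usual consistency constant
#' for a normal distribution.  Location and scale are computed over all
#' sample-well ratios of the replicate (experiment-wide by default; pass the
#' ratios of a single plate for per-plate scaling).
#'
#' @param ratios named numeric vector (pool or well -> normalized ratio),
#'   length >= 3.
#' @return named numeric vector of Z-scores.
#' @export
score_replicate <- function(ratios) {
  x <- as.numeric(ratios)
  if (length(x) < 3L) stop("need at least 3 sample ratios to score", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("ratios must be finite", call. = FALSE)
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med))
  if (mad_raw == 0) {
    stop("zero dispersion: MAD of ratios is 0, refusing division", call. = FALSE)
  }
  stats::setNames((x - med) / (1.4826 * mad_raw), names(ratios))
}

#' Summarize replicate scores per pool
#'
#' Combines per-replicate Z maps and per-replicate normalized ratios into one
#' record per pool: mean/min/max Z over the replicates in which the pool was
#' measured, and the mean normalized ratio ("fold rescue").  Pools measured
#' in fewer replicates than the maximum are flagged; pools present in the
#' library but in no replicate are returned in the `excluded` attribute.
#'
#' @param z_by_replicate list of named numeric vectors (pool -> Z), one per
#'   replicate.
#' @param ratios_by_replicate list of named numeric vectors (pool -> ratio),
#'   aligned with `z_by_replicate`.
#' @param library optional `sirna_library` supplying the pool -> gene map.
#' @return a `gene_score` data frame: `pool_id`, `gene`, `n_rep`, `mean_z`,
#'   `min_z`, `max_z`, `fold_rescue`, `flag`; attribute `excluded` lists
#'   library pools never measured.
#' @export
summarize_scores <- function(z_by_replicate, ratios_by_replicate, library = NULL) {
  stopifnot(is.list(z_by_replicate), is.list(ratios_by_replicate),
            length(z_by_replicate) == length(ratios_by_replicate))
  pools <- unique(unlist(lapply(z_by_replicate, names)))
  if (length(pools) == 0L) stop("no scored pools", call. = FALSE)
  n_max <- length(z_by_replicate)

  zmat <- sapply(z_by_replicate, function(z) z[pools])       # pools x reps
  rmat <- sapply(ratios_by_replicate, function(r) r[pools])
  zmat <- matrix(zmat, nrow = length(pools))
  rmat <- matrix(rmat, nrow = length(pools))

  n_rep <- rowSums(!is.na(zmat))
  mean_z <- rowMeans(zmat, na.rm = TRUE)
  min_z <- apply(zmat, 1L, min, na.rm = TRUE)
  max_z <- apply(zmat, 1L, max, na.rm = TRUE)
  fold <- rowMeans(rmat, na.rm = TRUE)
  flag <- ifelse(n_rep < n_max, paste0("n=", n_rep), "")

  gene <- rep(NA_character_, length(pools))
  excluded <- character(0)
  if (!is.null(library)) {
    map <- stats::setNames(library$gene, library$pool_id)
    map <- map[!duplicated(names(map))]
    gene <- unname(map[pools])
    excluded <- setdiff(unique(library$pool_id), pools)
  }
  out <- data.frame(pool_id = pools, gene = gene, n_rep = n_rep,
                    mean_z = mean_z, min_z = min_z, max_z = max_z,
                    fold_rescue = fold, flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  class(out) <- c("gene_score", "data.frame")
  out
}

#' Score a full screen bundle
#'
#' Convenience wrapper running [normalize_plate()] on every plate x replicate,
#' pooling each replicate's sample ratios experiment-wide (or per plate),
#' scoring with [score_replicate()] and summarizing with
#' [summarize_scores()].
#'
#' @param bundle a `screen_bundle`.
#' @param mode normalization mode, see [normalize_plate()].
#' @param scope `"experiment"` (default): Z location/scale over all sample
#'   wells of a replicate; `"plate"`: within each plate.
#' @return a `gene_score` data frame (see [summarize_scores()]); attribute
#'   `control_ratios` holds a data frame of normalized control wells.
#' @export
score_bundle <- function(bundle, mode = c("multiplicative", "additive"),
                         scope = c("experiment", "plate")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  stopifnot(inherits(bundle, "screen_bundle"))
  lay <- bundle$layout
  reps <- sort(unique(lay$replicate_id))

  z_list <- list()
  r_list <- list()
  ctrl <- list()
  for (rep_id in reps) {
    lr <- lay[lay$replicate_id == rep_id, , drop = FALSE]
    plates <- unique(lr$plate_id)
    per_plate <- lapply(plates, function(p) {
      normalize_plate(bundle$measurements, lr[lr$plate_id == p, , drop = FALSE],
                      mode = mode)
    })
    ratios <- unlist(lapply(per_plate, function(np) {
      stats::setNames(np$ratios, np$pools)     # key by pool id
    }))
    z <- if (scope == "experiment") {
      score_replicate(ratios)
    } else {
      unlist(lapply(per_plate, function(np) {
        score_replicate(stats::setNames(np$ratios, np$pools))
      }))
    }
    z_list[[rep_id]] <- z
    r_list[[rep_id]] <- ratios
    med <- stats::median(ratios)
    mad_raw <- stats::median(abs(ratios - med))
    ctrl[[rep_id]] <- do.call(rbind, lapply(per_plate, function(np) {
      if (length(np$control_ratios) == 0L) return(NULL)
      data.frame(plate_id = np$plate_id, replicate_id = rep_id,
                 well = names(np$control_ratios),
                 content_id = unname(np$control_content),
                 role = unname(np$control_roles),
                 ratio = unname(np$control_ratios),
                 z = (unname(np$control_ratios) - med) / (1.4826 * mad_raw),
                 stringsAsFactors = FALSE)
    }))
  }
  scores <- summarize_scores(z_list, r_list, bundle$library)
  attr(scores, "control_ratios") <- do.call(rbind, ctrl)
  scores
}

#' Mean Z-scores of control wells
#'
#' Control wells never enter the normalization median or the Z
#' location/scale, but they can be placed on the sample-well Z scale of each
#' replicate; this returns the mean of those Z values per control, averaged
#' over plates and replicates.  The minimum over scrambled controls is the
#' usual auto-derived counter-screen cutoff (see
#' [counterscreen_threshold()]).
#'
#' @param scores a `gene_score` from [score_bundle()] (carries the control
#'   table as an attribute).
#' @param role which control role to extract (default scrambled controls).
#' @return named numeric vector, control content id -> mean Z.
#' @export
control_scores <- function(scores, role = "scrambled_control") {
  ctrl <- attr(scores, "control_ratios")
  if (is.null(ctrl)) stop("scores carry no control table; use score_bundle()", call. = FALSE)
  ctrl <- ctrl[ctrl$role == role, , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("no control wells with role '", role, "'", call. = FALSE)
  means <- tapply(ctrl$z, ctrl$content_id, mean)
  stats::setNames(as.numeric(means), names(means))
}
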