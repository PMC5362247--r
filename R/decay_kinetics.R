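# Decay kinetics: relative quantification of shutoff time courses and
# log-linear (semi-log) half-life estimation.  Used for mRNA decay after
# transcription shutoff (qPCR against a reference RNA such as 18S rRNA,
# which RNA-polymerase-II inhibition leaves untouched) and, identically, for
# protein decay from densitometry after translation shutoff.

#' Construct a decay time course
#'
#' @param time numeric vector of times (minutes, >= 0, strictly increasing).
#' @param abundance numeric vector of relative abundances (> 0).  When a
#'   t = 0 point is present the series is renormalized so that it equals 1.
#' @param label optional condition label (e.g. "+dox").
#' @return a `decay_timecourse` data frame with columns `time`, `abundance`.
#' @export
decay_timecourse <- function(time, abundance, label = "") {
  stopifnot(length(time) == length(abundance))
  if (anyNA(time) || anyNA(abundance)) stop("time course contains NA", call. = FALSE)
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(abundance <= 0)) {
    stop("abundances must be positive (cannot take log of <= 0)", call. = FALSE)
  }
  if (any(time == 0)) abundance <- abundance / abundance[time == 0]
  structure(data.frame(time = time, abundance = abundance),
            label = label, class = c("decay_timecourse", "data.frame"))
}

#' Relative quantification of a qPCR shutoff time course
#'
#' Standard 2^-ddCt quantification: for each time point,
#' `abundance(t) = 2^-[(Ct_target(t) - Ct_ref(t)) - (Ct_target(0) - Ct_ref(0))]`,
#' so the t = 0 abundance is exactly 1.  The reference channel (e.g. 18S
#' rRNA) is mandatory and must share the target's time grid.
#'
#' @param time numeric vector of times (minutes); must include 0.
#' @param ct_target,ct_reference Ct values on the same time grid.
#' @param label optional condition label.
#' @return a `decay_timecourse`.
#' @export
relative_quantity <- function(time, ct_target, ct_reference, label = "") {
  if (length(ct_target) != length(time) || length(ct_reference) != length(time)) {
    stop("target and reference Ct series must align with the time grid", call. = FALSE)
  }
  if (anyNA(ct_target) || anyNA(ct_reference) ||
      any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (!any(time == 0)) stop("qPCR time course must include t = 0", call. = FALSE)
  dct <- ct_target - ct_reference
  ddct <- dct - dct[time == 0][1L]
  decay_timecourse(time, 2^(-ddct), label = label)
}

#' Fit first-order decay on a semi-log plot
#'
#' Ordinary least squares of `ln(abundance)` on time.  The decay rate is
#' `k = -slope` (1/min) and the half-life `t1/2 = ln(2)/k`.  Slopes within
#' `k_tol` of zero, or positive trends, are reported as non-decaying with an
#' undefined half-life rather than as errors.  A nonlinear exponential fit
#' (`method = "nls"`, minimizing squared error on the natural scale) is
#' available for comparison.
#'
#' @param tc a `decay_timecourse` (or data frame with `time`, `abundance`),
#'   >= 3 points.
#' @param method `"ols"` (log-linear, default) or `"nls"`.
#' @param k_tol rates below this are treated as non-decaying (default
#'   1e-6 / min).
#' @return a `decay_fit` list: `k`, `half_life`, `intercept` (log-abundance
#'   at t = 0), `r_squared` (log-space, clamped to `[0, 1]` with
#'   `r_squared_clamped` flag), `non_decaying`, `n`, `method`.
#' @export
fit_decay <- function(tc, method = c("ols", "nls"), k_tol = 1e-6) {
  method <- match.arg(method)
  if (!is.data.frame(tc) || !all(c("time", "abundance") %in% names(tc))) {
    stop("fit_decay() expects a decay_timecourse", call. = FALSE)
  }
  if (nrow(tc) < 3L) stop("need >= 3 time points to fit a decay", call. = FALSE)
  if (any(tc$abundance <= 0)) stop("abundances must be positive", call. = FALSE)

  ly <- log(tc$abundance)
  fit <- stats::lm(ly ~ tc$time)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (method == "nls") {
    nl <- try(stats::nls(abundance ~ exp(a - k * time), data = tc,
                         start = list(a = intercept, k = max(-slope, k_tol))),
              silent = TRUE)
    if (!inherits(nl, "try-error")) {
      slope <- -unname(stats::coef(nl)["k"])
      intercept <- unname(stats::coef(nl)["a"])
    }
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  clamped <- r2 < 0
  r2 <- min(max(r2, 0), 1)

  k <- -slope
  non_decaying <- k <= k_tol
  structure(list(k = if (non_decaying) k else k,
                 half_life = if (non_decaying) NA_real_ else log(2) / k,
                 intercept = intercept,
                 r_squared = r2, r_squared_clamped = clamped,
                 non_decaying = non_decaying,
                 n = nrow(tc), method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$non_decaying) {
    cat(sprintf("Decay fit (%s, n=%d): non-decaying (k = %.3g/min)\n",
                x$method, x$n, x$k))
  } else {
    cat(sprintf("Decay fit (%s, n=%d): k = %.4g/min, t1/2 = %.4g min, r2 = %.3f\n",
                x$method, x$n, x$k, x$half_life, x$r_squared))
  }
  invisible(x)
}
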