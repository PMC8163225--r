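#' Construct a feature run (injection sequence with QC annotations)
#'
#' Container for one LC-MS acquisition sequence prior to network assembly:
#' per injection, a sample id, a role (`sample`, `QC` for the pooled
#' quality-control sample, `dQC` for its dilution), a batch index and an
#' injection order, together with the feature intensity vector. QCs drive
#' drift correction ([loess_normalize()]); dQC/QC ratios drive reliability
#' filtering ([qc_ratio_filter()]).
#'
#' @param meta data frame with columns `sample_id`, `role`, `batch`,
#'   `order` (injection order, unique within batch).
#' @param intensities numeric matrix, one row per injection (same order as
#'   `meta`), one column per feature.
#' @return an object of class `"feature_run"`.
#' @export
feature_run <- function(meta, intensities) {
  need <- c("sample_id", "role", "batch", "order")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("'meta' must have columns: ", paste(need, collapse = ", "))
  if (!all(meta$role %in% c("sample", "QC", "dQC")))
    stop("'role' must be one of sample, QC, dQC")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(meta))
    stop("'intensities' must have one row per injection")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("F", seq_len(ncol(intensities)))
  for (b in unique(meta$batch)) {
    sel <- meta$batch == b
    if (anyDuplicated(meta$order[sel]))
      stop("injection orders are not unique within batch ", b)
    if (sum(meta$role[sel] == "QC") < 2L)
      stop("batch ", b, " has fewer than 2 QC injections")
  }
  structure(list(meta = meta, intensities = intensities),
            class = "feature_run")
}

#' @export
print.feature_run <- function(x, ...) {
  cat(sprintf("<feature_run> %d injections (%d samples, %d QC, %d dQC), %d batches, %d features\n",
              nrow(x$meta), sum(x$meta$role == "sample"),
              sum(x$meta$role == "QC"), sum(x$meta$role == "dQC"),
              length(unique(x$meta$batch)), ncol(x$intensities)))
  invisible(x)
}

# fit a QC drift curve for one feature within one batch and evaluate it at
# the requested injection orders; boundary orders reuse the nearest fitted
# value (no extrapolation). Falls back to a linear fit when too few QCs
# support a local regression.
fit_drift <- function(qc_order, qc_y, at, span) {
  o <- order(qc_order)
  qc_order <- qc_order[o]; qc_y <- qc_y[o]
  at_cl <- pmin(pmax(at, min(qc_order)), max(qc_order))
  if (length(unique(qc_y)) == 1L) return(rep(qc_y[1L], length(at)))
  fit <- NULL
  if (length(qc_order) >= 4L) {
    fit <- tryCatch(
      stats::loess(qc_y ~ qc_order, span = span, degree = 1L,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(fit)) {
    lm_fit <- stats::lm(qc_y ~ qc_order)
    return(unname(stats::predict(lm_fit,
                                 data.frame(qc_order = at_cl))))
  }
  unname(stats::predict(fit, data.frame(qc_order = at_cl)))
}

#' LOESS signal-drift and batch normalization
#'
#' Two-stage QC-anchored normalization. Intra-batch: per feature and
#' batch, a locally weighted (degree-1 LOESS) regression of QC intensity
#' on injection order gives a drift curve; every injection is divided by
#' the drift value at its order and multiplied by the batch QC median.
#' Inter-batch: each batch is then rescaled by (global QC median / batch
#' QC median), so that after correction every batch's QC median equals the
#' global QC median. Features whose QC signal is entirely zero or whose
#' drift curve touches zero cannot be normalized; they are passed through
#' unchanged and reported with a warning.
#'
#' @param run a [feature_run()].
#' @param span LOESS span (default 0.75, degree 1); boundary injections
#'   reuse the nearest fitted value rather than extrapolating.
#' @param burn_in number of leading injections per batch excluded from
#'   drift fitting (system-conditioning injections); default 0.
#' @return a [feature_run()] with corrected intensities; unnormalizable
#'   feature ids are attached as the `"unnormalizable"` attribute.
#' @export
loess_normalize <- function(run, span = 0.75, burn_in = 0L) {
  stopifnot(inherits(run, "feature_run"))
  meta <- run$meta
  X <- run$intensities
  feats <- colnames(X)
  batches <- unique(meta$batch)
  bad <- character(0)

  for (b in batches) {
    sel <- which(meta$batch == b)
    ord <- meta$order[sel]
    keep_fit <- ord > (min(ord) - 1L + burn_in)  # drop burn-in injections
    qc <- sel[meta$role[sel] == "QC" & keep_fit]
    if (length(qc) < 2L)
      stop("batch ", b, " has fewer than 2 usable QC injections for drift fitting")
    for (f in feats) {
      y <- X[qc, f]
      if (all(y == 0)) { bad <- c(bad, f); next }
      drift <- fit_drift(meta$order[qc], y, meta$order[sel], span)
      if (any(!is.finite(drift)) || any(drift <= 0)) { bad <- c(bad, f); next }
      med <- stats::median(y)
      X[sel, f] <- X[sel, f] / drift * med
    }
  }

  # inter-batch: bring every batch's QC median to the global QC median
  qc_all <- which(meta$role == "QC")
  for (f in setdiff(feats, bad)) {
    gmed <- stats::median(X[qc_all, f])
    for (b in batches) {
      sel <- which(meta$batch == b)
      bq <- sel[meta$role[sel] == "QC"]
      bmed <- stats::median(X[bq, f])
      if (bmed > 0) X[sel, f] <- X[sel, f] * gmed / bmed
    }
  }
  bad <- unique(bad)
  if (length(bad))
    warning("feature(s) not normalizable (flat or zero QC signal): ",
            paste(bad, collapse = ", "))
  out <- run
  out$intensities <- X
  attr(out, "unnormalizable") <- bad
  out
}

#' Filter unreliable features by dQC/QC ratio behaviour
#'
#' Each dQC injection is paired with its nearest QC injection (by
#' injection order, within batch). Per feature, the dQC/QC intensity
#' ratios over these pairs must be both stable and consistent with the
#' dilution: a feature is retained iff the relative standard deviation of
#' its ratio series is at most `rsd_threshold` percent AND its median
#' ratio lies within `[ratio_low, ratio_high]`. Features failing either
#' rule — or with undefined ratios — are removed and reported for audit.
#'
#' @param run a [feature_run()] containing dQC injections.
#' @param rsd_threshold maximum ratio RSD in percent (default 50).
#' @param ratio_low,ratio_high admissible window for the median dQC/QC
#'   ratio (defaults 0.2 and 0.8).
#' @return list with elements `run` (filtered [feature_run()]) and
#'   `removed` (character vector of removed feature ids).
#' @export
qc_ratio_filter <- function(run, rsd_threshold = 50,
                            ratio_low = 0.2, ratio_high = 0.8) {
  stopifnot(inherits(run, "feature_run"))
  meta <- run$meta
  dqc <- which(meta$role == "dQC")
  if (length(dqc) == 0L)
    stop("no dQC injections: the dQC/QC ratio filter cannot be evaluated")
  # pair every dQC with the closest QC of its batch (ties -> earlier QC)
  pairs <- do.call(rbind, lapply(dqc, function(i) {
    qc <- which(meta$role == "QC" & meta$batch == meta$batch[i])
    d <- abs(meta$order[qc] - meta$order[i])
    j <- qc[order(d, meta$order[qc])][1L]
    c(dqc = i, qc = j)
  }))
  ratios <- run$intensities[pairs[, "dqc"], , drop = FALSE] /
            run$intensities[pairs[, "qc"], , drop = FALSE]
  keep <- vapply(seq_len(ncol(ratios)), function(f) {
    r <- ratios[, f]
    if (any(!is.finite(r))) return(FALSE)
    m <- mean(r)
    rsd <- if (m == 0) Inf else 100 * stats::sd(r) / abs(m)
    if (length(r) == 1L) rsd <- 0
    med <- stats::median(r)
    rsd <= rsd_threshold && med >= ratio_low && med <= ratio_high
  }, logical(1))
  removed <- colnames(run$intensities)[!keep]
  out <- run
  out$intensities <- run$intensities[, keep, drop = FALSE]
  list(run = out, removed = removed)
}
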