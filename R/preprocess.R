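#' Filter proteins on per-fraction observation frequency
#'
#' Retains a protein if it is observed in at least
#' `ceiling(min_obs_frac * n_samples)` samples of at least one density
#' fraction. This keeps fraction-selective proteins (fully observed in one
#' fraction, absent elsewhere) that a global completeness filter would drop,
#' which is the point of the downstream MNAR handling.
#'
#' @param m An [lfq_matrix()].
#' @param min_obs_frac Minimum fraction of a density fraction's samples in
#'   which a protein must be observed (default 0.5).
#' @return The filtered [lfq_matrix()], with the dropped accessions in
#'   `attr(, "dropped")`.
#' @export
filter_proteins <- function(m, min_obs_frac = 0.5) {
  stopifnot(inherits(m, "lfq_matrix"))
  obs <- !is.na(m$values)
  keep <- rep(FALSE, nrow(obs))
  for (f in unique(m$design$fraction)) {
    cols <- m$design$fraction == f
    need <- ceiling(min_obs_frac * sum(cols))
    keep <- keep | rowSums(obs[, cols, drop = FALSE]) >= need
  }
  out <- lfq_matrix(m$values[keep, , drop = FALSE], m$design, m$normalized)
  attr(out, "dropped") <- rownames(m$values)[!keep]
  out
}

#' Variance-stabilizing normalization
#'
#' Two-step variance stabilization for log2 LFQ intensities: a generalized
#' log transform with a common low-intensity offset applied on the linear
#' scale (compressing the inflated variance of low-abundance proteins),
#' followed by per-sample affine calibration to a common median and spread.
#' The transform is strictly monotone within every sample, so ranks are
#' preserved, and post-normalization sample medians agree exactly.
#'
#' @param m An [lfq_matrix()] on log2 scale.
#' @param glog_quantile Quantile of the linear-scale intensities used as the
#'   glog offset (default 0.05); larger values stabilize more aggressively.
#' @return The normalized [lfq_matrix()] (`normalized = TRUE`); the missing
#'   mask is unchanged.
#' @export
vsn_normalize <- function(m, glog_quantile = 0.05) {
  stopifnot(inherits(m, "lfq_matrix"))
  x <- m$values
  if (ncol(x) < 2) stop("normalization needs at least 2 samples")
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  lin <- 2^x
  c0 <- quantile(lin, glog_quantile, na.rm = TRUE, names = FALSE)
  g <- log2((lin + sqrt(lin^2 + c0^2)) / 2)
  med <- apply(g, 2, median, na.rm = TRUE)
  sc <- apply(g, 2, mad, na.rm = TRUE)
  sc[!is.finite(sc) | sc == 0] <- 1
  ref_med <- median(med)
  ref_sc <- median(sc)
  if (ref_sc == 0) ref_sc <- 1
  y <- sweep(g, 2, med, "-")
  y <- sweep(y, 2, ref_sc / sc, "*")
  y <- y + ref_med
  lfq_matrix(y, m$design, normalized = TRUE)
}
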