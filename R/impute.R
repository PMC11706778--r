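#' Per-fraction MNAR log2-intensity cutoffs
#'
#' Default classification cutoffs for the eight density fractions of the
#' reference design, determined on the real data with the simulation curve
#' as a guide.
#'
#' @return Named numeric vector, names `"1"`..`"8"`.
#' @export
default_fraction_cutoffs <- function() {
  c(`1` = 14.9, `2` = 14.7, `3` = 14.9, `4` = 14.3,
    `5` = 14.6, `6` = 14.5, `7` = 15.3, `8` = 15.2)
}

#' Read per-fraction cutoffs from a YAML file
#'
#' The file maps fraction number to log2-intensity cutoff, e.g. `"4": 14.3`.
#'
#' @param path YAML file path.
#' @return Named numeric vector.
#' @export
read_cutoffs <- function(path) {
  y <- yaml::read_yaml(path)
  out <- unlist(y)
  storage.mode(out) <- "double"
  out
}

expand_cutoffs <- function(cutoffs, fractions) {
  fractions <- sort(unique(as.integer(fractions)))
  if (is.null(names(cutoffs))) {
    if (length(cutoffs) == 1) {
      cutoffs <- setNames(rep(cutoffs, length(fractions)), fractions)
    } else if (length(cutoffs) == length(fractions)) {
      names(cutoffs) <- fractions
    } else {
      stop("unnamed cutoffs must be length 1 or one per fraction")
    }
  }
  miss <- setdiff(as.character(fractions), names(cutoffs))
  if (length(miss)) {
    stop("no cutoff for fraction(s): ", paste(miss, collapse = ", "))
  }
  cutoffs[as.character(fractions)]
}

#' Classify missing cells as MNAR or MAR
#'
#' For each protein x fraction with at least one missing cell: if the
#' protein has no observed value anywhere in that fraction it is treated as
#' absent from the fraction and all its missing cells there are MNAR;
#' otherwise the protein's mean observed intensity within the fraction is
#' compared with the fraction's cutoff -- below the cutoff the missing cells
#' are MNAR (below-detection censoring), at or above it they are MAR.
#'
#' @param m A normalized [lfq_matrix()].
#' @param cutoffs Per-fraction log2 cutoffs (named by fraction), a single
#'   number applied to every fraction, or the default
#'   [default_fraction_cutoffs()].
#' @return Data frame of class `missingness_classification` with one row per
#'   missing cell: `protein`, `sample`, `fraction`, `label`
#'   (`"MNAR"`/`"MAR"`), `basis` (the fraction mean, `NA` when absent),
#'   `absent`.
#' @export
classify_missingness <- function(m, cutoffs = default_fraction_cutoffs()) {
  stopifnot(inherits(m, "lfq_matrix"))
  vals <- m$values
  fr <- m$design$fraction
  cutoffs <- expand_cutoffs(cutoffs, fr)
  out <- list()
  for (f in sort(unique(fr))) {
    cols <- which(fr == f)
    sub <- vals[, cols, drop = FALSE]
    miss <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(miss) == 0) next
    nobs <- rowSums(!is.na(sub))
    fmean <- rowMeans(sub, na.rm = TRUE)
    absent <- nobs[miss[, 1]] == 0
    basis <- ifelse(absent, NA_real_, fmean[miss[, 1]])
    label <- ifelse(absent | basis < cutoffs[as.character(f)], "MNAR", "MAR")
    out[[length(out) + 1]] <- data.frame(
      protein = rownames(sub)[miss[, 1]],
      sample = colnames(sub)[miss[, 2]],
      fraction = f, label = label, basis = basis, absent = absent,
      stringsAsFactors = FALSE)
  }
  cls <- if (length(out)) do.call(rbind, out) else
    data.frame(protein = character(0), sample = character(0),
               fraction = integer(0), label = character(0),
               basis = numeric(0), absent = logical(0))
  rownames(cls) <- NULL
  class(cls) <- c("missingness_classification", "data.frame")
  cls
}

#' Impute MNAR cells with a left-shifted Gaussian draw
#'
#' Each MNAR cell of sample *s* is drawn from
#' `N(mu_s - shift * sigma_s, (width * sigma_s)^2)`, where `mu_s` and
#' `sigma_s` are the mean and SD of the sample's observed values -- the
#' below-detection convention used by mainstream proteomics tools. Draws are
#' made sample by sample (column order, row order within a sample) so a
#' fixed seed gives a reproducible matrix.
#'
#' @param m An [lfq_matrix()].
#' @param cls Classification from [classify_missingness()].
#' @param shift,width Down-shift and width of the draw, in units of the
#'   sample SD (defaults 1.8 and 0.3).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return The [lfq_matrix()] with MNAR cells filled; observed cells are
#'   untouched.
#' @export
impute_mnar <- function(m, cls, shift = 1.8, width = 0.3, seed = NULL) {
  stopifnot(inherits(m, "lfq_matrix"))
  vals <- m$values
  if (!is.null(seed)) set.seed(seed)
  mnar <- cls[cls$label == "MNAR", , drop = FALSE]
  if (nrow(mnar) == 0) return(m)
  n_obs <- colSums(!is.na(vals))
  need <- unique(mnar$sample)
  thin <- need[n_obs[need] < 3]
  if (length(thin)) {
    stop("sample(s) with fewer than 3 observed values, moments unreliable: ",
         paste(thin, collapse = ", "))
  }
  for (j in seq_len(ncol(vals))) {
    s <- colnames(vals)[j]
    rows <- mnar$protein[mnar$sample == s]
    if (!length(rows)) next
    idx <- match(rows, rownames(vals))
    # key the draw order to protein names, not row positions, so results do
    # not depend on the row order of the input matrix
    idx <- idx[order(rownames(vals)[idx])]
    mu <- mean(vals[, j], na.rm = TRUE)
    sig <- sd(vals[, j], na.rm = TRUE)
    vals[idx, j] <- rnorm(length(idx), mu - shift * sig, width * sig)
  }
  lfq_matrix(vals, m$design, m$normalized)
}

#' Impute MAR cells by k-nearest-neighbour row averaging
#'
#' For each protein row with MAR cells, the Euclidean distance (mean squared
#' difference over jointly observed samples) to every other row is computed;
#' each MAR cell is filled with the mean of the same cell position across
#' the `k` nearest rows that carry a value there. Rows with no eligible
#' neighbour fall back to the protein's mean over its own fraction group
#' (recorded in `attr(, "fallback")`).
#'
#' @param m An [lfq_matrix()] (typically after [impute_mnar()]).
#' @param cls Classification from [classify_missingness()].
#' @param k Number of neighbour rows (default 10).
#' @return The [lfq_matrix()] with MAR cells filled.
#' @export
impute_mar <- function(m, cls, k = 10) {
  stopifnot(inherits(m, "lfq_matrix"))
  vals <- m$values
  mar <- cls[cls$label == "MAR", , drop = FALSE]
  if (nrow(mar) == 0) return(m)
  fallback <- character(0)
  groups <- m$design$group
  targets <- unique(mar$protein)
  src <- vals  # distances and neighbour values come from the input matrix,
               # so the result does not depend on target processing order
  for (p in targets) {
    i <- match(p, rownames(src))
    d <- rowMeans(sweep(src, 2, src[i, ], "-")^2, na.rm = TRUE)
    d[i] <- Inf
    d[is.nan(d)] <- Inf  # no jointly observed samples
    ord <- order(d, rownames(src))  # name-keyed tie-break
    cols <- match(mar$sample[mar$protein == p], colnames(src))
    for (jc in cols) {
      nb <- ord[is.finite(d[ord]) & !is.na(src[ord, jc])]
      if (length(nb) >= 1) {
        nb <- nb[seq_len(min(k, length(nb)))]
        vals[i, jc] <- mean(src[nb, jc])
      } else {
        gv <- src[i, groups == groups[jc]]
        vals[i, jc] <- mean(gv, na.rm = TRUE)
        fallback <- c(fallback, paste0(p, ":", colnames(src)[jc]))
      }
    }
  }
  out <- lfq_matrix(vals, m$design, m$normalized)
  attr(out, "fallback") <- fallback
  out
}

#' Hybrid MNAR/MAR imputation
#'
#' The core strategy: classify each missing cell from per-fraction intensity
#' cutoffs ([classify_missingness()]), impute MNAR cells with a left-shifted
#' Gaussian draw ([impute_mnar()]) and MAR cells by row-wise kNN averaging
#' ([impute_mar()]). Designed to keep proteins expressed selectively in one
#' or two fraction groups in the analysis instead of discarding them.
#'
#' @inheritParams impute_mnar
#' @inheritParams impute_mar
#' @param cutoffs Per-fraction cutoffs as in [classify_missingness()].
#' @return List with `imputed` (an [lfq_matrix()] with no missing cells),
#'   `classification`, and `report` (missing-cell counts per label per
#'   fraction, kNN fallbacks, the seed).
#' @export
hybrid_impute <- function(m, cutoffs = default_fraction_cutoffs(),
                          shift = 1.8, width = 0.3, k = 10, seed = NULL) {
  cls <- classify_missingness(m, cutoffs)
  imp <- impute_mnar(m, cls, shift = shift, width = width, seed = seed)
  imp <- impute_mar(imp, cls, k = k)
  counts <- table(factor(cls$label, levels = c("MNAR", "MAR")), cls$fraction)
  report <- list(n_missing = nrow(cls),
                 counts_by_fraction = as.data.frame.matrix(counts),
                 n_fallback = length(attr(imp, "fallback")),
                 fallback = attr(imp, "fallback"),
                 seed = seed)
  stopifnot(!anyNA(imp$values))
  list(imputed = imp, classification = cls, report = report)
}
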