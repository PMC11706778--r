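#' True-MNAR share of missing cells along the intensity axis
#'
#' Bins proteins by their true mean intensity (complete matrix) and, within
#' each bin, computes the proportion of missing cells whose truth label is
#' MNAR. The resulting curve is high in the censored low-intensity regime
#' and falls to the random-missingness floor above it; its decline locates
#' the MNAR classification cutoff.
#'
#' @param study A `simulated_study` with truth labels.
#' @param bin_width Bin width on the protein-mean log2 axis (default 0.5).
#' @return Data frame `bin_mid`, `n_missing`, `n_mnar`, `prop_mnar`;
#'   bins with no missing cells are omitted.
#' @export
missingness_curve <- function(study, bin_width = 0.5) {
  if (is.null(study$missingness)) stop("study has no injected missingness")
  pmean <- rowMeans(study$complete$values)
  lab <- study$missingness
  miss <- lab != "observed"
  cell_mean <- pmean[row(lab)[miss]]
  cell_lab <- lab[miss]
  breaks <- seq(floor(min(pmean) / bin_width) * bin_width,
                ceiling(max(pmean) / bin_width) * bin_width, by = bin_width)
  bin <- cut(cell_mean, breaks = breaks, include.lowest = TRUE)
  n_missing <- tapply(cell_lab, bin, length)
  n_mnar <- tapply(cell_lab == "MNAR", bin, sum)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- !is.na(n_missing) & n_missing > 0
  data.frame(bin_mid = mids[keep],
             n_missing = as.integer(n_missing[keep]),
             n_mnar = as.integer(n_mnar[keep]),
             prop_mnar = as.numeric(n_mnar[keep] / n_missing[keep]),
             row.names = NULL)
}

#' Select the MNAR cutoff from a missingness curve
#'
#' Operationalizes "the bottom of the steep decline": scanning the bins in
#' increasing intensity, returns the centre of the first bin from which the
#' MNAR share stays below `epsilon`. If the curve never reaches `epsilon`
#' there is no MNAR regime and `NA` is returned with a message attribute.
#'
#' @param curve Data frame from [missingness_curve()] (columns `bin_mid`,
#'   `prop_mnar`).
#' @param epsilon Threshold on the MNAR share (default 0.05).
#' @return Log2-intensity cutoff (a bin centre), or `NA_real_` sentinel.
#' @export
select_cutoff <- function(curve, epsilon = 0.05) {
  if (nrow(curve) == 0) stop("empty curve")
  ord <- order(curve$bin_mid)
  prop <- curve$prop_mnar[ord]
  mid <- curve$bin_mid[ord]
  if (!any(prop >= epsilon)) {
    return(structure(NA_real_, note = "no MNAR regime: curve never exceeds epsilon"))
  }
  last_above <- max(which(prop >= epsilon))
  if (last_above == length(prop)) {
    return(structure(NA_real_, note = "curve never settles below epsilon"))
  }
  mid[last_above + 1]
}

#' Benchmark an analysis strategy on a simulated study
#'
#' Runs one of three strategies on a study with known truth and scores it:
#' `"hybrid"` imputes with [hybrid_impute()] at the given cutoff and tests
#' everything; `"unimputed"` tests observed values only (proteins with at
#' least 2 observations per group); `"complete_case"` first drops every
#' protein with any missing cell. Capture is the percentage of all planted
#' DEPs called significant (BH-adjusted moderated F p < `alpha`), accuracy
#' the percentage of true DEPs among significant calls (precision), and the
#' mean adjusted F p over tested true DEPs is reported as the third figure
#' of merit (smaller is better).
#'
#' @param study A `simulated_study` with injected missingness.
#' @param strategy One of `"hybrid"`, `"unimputed"`, `"complete_case"`.
#' @param cutoff MNAR classification cutoff (log2 units) for the hybrid
#'   strategy (default 12; a single simulation-wide value).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param seed Seed for the MNAR imputation draw.
#' @return One-row data frame: `strategy`, `n_tested`, `n_called`,
#'   `capture`, `accuracy`, `mean_adj_p_dep`.
#' @export
evaluate_strategy <- function(study, strategy = c("hybrid", "unimputed",
                                                  "complete_case"),
                              cutoff = 12, alpha = 0.05, seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.null(study$observed)) stop("study has no injected missingness")
  n_dep <- sum(study$dep$is_dep)
  m <- switch(strategy,
    hybrid = hybrid_impute(study$observed, cutoffs = cutoff,
                           seed = seed)$imputed,
    unimputed = study$observed,
    complete_case = {
      keep <- rowSums(is.na(study$observed$values)) == 0
      lfq_matrix(study$observed$values[keep, , drop = FALSE],
                 study$observed$design, normalized = TRUE)
    })
  if (nrow(m$values) == 0) stop("no testable proteins under strategy ", strategy)
  res <- run_contrasts(m, alpha = alpha)
  if (!any(!is.na(res$adj_p_F))) {
    stop("no testable proteins under strategy ", strategy)
  }
  truth <- study$dep$is_dep[match(res$protein, study$dep$protein)]
  called <- res$significant
  hits <- sum(called & truth)
  dep_p <- res$adj_p_F[truth & !is.na(res$adj_p_F)]
  data.frame(strategy = strategy,
             n_tested = sum(!is.na(res$adj_p_F)),
             n_called = sum(called),
             capture = 100 * hits / n_dep,
             accuracy = if (sum(called) > 0) 100 * hits / sum(called)
                        else NA_real_,
             mean_adj_p_dep = if (length(dep_p)) mean(dep_p) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare the hybrid, unimputed and complete-case strategies
#'
#' @inheritParams evaluate_strategy
#' @return Data frame with one [evaluate_strategy()] row per strategy.
#' @export
compare_strategies <- function(study, cutoff = 12, alpha = 0.05, seed = 1L) {
  do.call(rbind, lapply(c("hybrid", "unimputed", "complete_case"),
                        function(s) evaluate_strategy(study, s, cutoff = cutoff,
                                                      alpha = alpha,
                                                      seed = seed)))
}

#' Sweep the MNAR cutoff over a grid
#'
#' Evaluates the hybrid strategy at each cutoff of a grid (default:
#' 0.1-log2-unit steps over the observed intensity range). Intended for
#' reduced-scale simulations; the full design is expensive to sweep.
#'
#' @inheritParams evaluate_strategy
#' @param grid Numeric vector of cutoffs; `NULL` for the default grid.
#' @param grid_step Step used when `grid` is `NULL`.
#' @return Data frame: one row per cutoff with the [evaluate_strategy()]
#'   scores.
#' @export
cutoff_sweep <- function(study, grid = NULL, grid_step = 0.1, alpha = 0.05,
                         seed = 1L) {
  if (is.null(grid)) {
    rng <- range(study$observed$values, na.rm = TRUE)
    grid <- seq(rng[1], rng[2], by = grid_step)
  }
  rows <- lapply(grid, function(co) {
    row <- evaluate_strategy(study, "hybrid", cutoff = co, alpha = alpha,
                             seed = seed)
    cbind(cutoff = co, row)
  })
  do.call(rbind, rows)
}
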