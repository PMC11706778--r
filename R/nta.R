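#' Binned particle size distribution
#'
#' Container for nanoparticle tracking analysis (NTA) exports: per-bin
#' particle concentrations on the instrument's 5-nm diameter grid, possibly
#' over several technical replicates, with the dilution factor and the wet
#' tissue mass the sample came from as metadata.
#'
#' @param data Data frame with columns `bin_center_nm`, `concentration` and
#'   optionally `replicate` (defaults to 1).
#' @param dilution Dilution factor applied before reading (>= 1 means the
#'   instrument saw a diluted sample); 1 once normalized.
#' @param tissue_mg Wet tissue mass in mg, or `NA`.
#' @return Object of class `size_distribution` (a data frame with
#'   attributes `dilution` and `tissue_mg`).
#' @export
size_distribution <- function(data, dilution = 1, tissue_mg = NA_real_) {
  stopifnot(all(c("bin_center_nm", "concentration") %in% names(data)))
  if (is.null(data$replicate)) data$replicate <- 1L
  if (any(data$concentration < 0)) stop("negative concentrations")
  if (dilution <= 0) stop("dilution factor must be positive")
  for (r in unique(data$replicate)) {
    b <- sort(data$bin_center_nm[data$replicate == r])
    if (anyDuplicated(b)) stop("duplicate bins within replicate ", r)
    if (length(b) > 1 && any(abs(diff(b) %% 5) > 1e-9 & abs(diff(b) %% 5 - 5) > 1e-9)) {
      stop("bins must lie on a 5-nm grid")
    }
  }
  data <- data[order(data$replicate, data$bin_center_nm),
               c("bin_center_nm", "concentration", "replicate")]
  rownames(data) <- NULL
  structure(data, dilution = dilution, tissue_mg = tissue_mg,
            class = c("size_distribution", "data.frame"))
}

#' Read an NTA export
#'
#' CSV with columns `bin_center_nm`, `concentration`, optional `replicate`
#' and `dilution` (constant per file).
#'
#' @param path CSV path.
#' @return A [size_distribution()].
#' @export
read_nta_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  dilution <- if ("dilution" %in% names(tab)) unique(tab$dilution) else 1
  if (length(dilution) != 1) stop("dilution must be constant within a file")
  tab$dilution <- NULL
  size_distribution(tab, dilution = dilution)
}

rebuild <- function(d, data, dilution = attr(d, "dilution"),
                    tissue_mg = attr(d, "tissue_mg")) {
  size_distribution(data, dilution = dilution, tissue_mg = tissue_mg)
}

#' Undo sample dilution
#'
#' Multiplies every bin concentration by the dilution factor and clears it
#' from the metadata.
#'
#' @param d A [size_distribution()].
#' @return The normalized [size_distribution()] (`dilution = 1`).
#' @export
normalize_dilution <- function(d) {
  dat <- as.data.frame(d)
  dat$concentration <- dat$concentration * attr(d, "dilution")
  rebuild(d, dat, dilution = 1)
}

#' Scale concentrations to particles per mg of tissue
#'
#' @param d A [size_distribution()].
#' @param tissue_mg Wet tissue mass in mg (positive).
#' @return The scaled [size_distribution()] with `tissue_mg` recorded.
#' @export
scale_per_mg <- function(d, tissue_mg) {
  if (!is.finite(tissue_mg) || tissue_mg <= 0) stop("tissue mass must be positive")
  dat <- as.data.frame(d)
  dat$concentration <- dat$concentration / tissue_mg
  rebuild(d, dat, tissue_mg = tissue_mg)
}

#' Aggregate technical replicates
#'
#' Element-wise mean (for per-mg concentration summaries) or sum (the
#' convention for mode estimation from pooled counts) over replicates on an
#' identical bin grid.
#'
#' @param d A [size_distribution()] containing one or more replicates.
#' @param method `"mean"` or `"sum"`.
#' @return A single-replicate [size_distribution()].
#' @export
aggregate_replicates <- function(d, method = c("mean", "sum")) {
  method <- match.arg(method)
  dat <- as.data.frame(d)
  grids <- split(dat$bin_center_nm, dat$replicate)
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1) {
    stop("replicates must share an identical bin grid")
  }
  agg <- tapply(dat$concentration, dat$bin_center_nm,
                if (method == "mean") mean else sum)
  out <- data.frame(bin_center_nm = as.numeric(names(agg)),
                    concentration = as.numeric(agg), replicate = 1L)
  rebuild(d, out)
}

single_replicate <- function(d) {
  if (length(unique(d$replicate)) > 1) {
    stop("aggregate replicates first")
  }
  as.data.frame(d)
}

#' Mode diameter
#'
#' Bin centre with the highest concentration; ties break towards the
#' smaller diameter.
#'
#' @param d A single-replicate [size_distribution()].
#' @return Diameter in nm.
#' @export
mode_diameter <- function(d) {
  dat <- single_replicate(d)
  cand <- dat$bin_center_nm[dat$concentration == max(dat$concentration)]
  min(cand)
}

#' Percentile diameters (D10, D50, D90, ...)
#'
#' Diameters below which `q` of the particle mass lies, from the cumulative
#' concentration-weighted distribution with linear interpolation inside the
#' crossing 5-nm bin (bin `c` spans `c - 2.5` to `c + 2.5` nm).
#'
#' @param d A single-replicate [size_distribution()].
#' @param q Probabilities in (0, 1), e.g. `c(0.1, 0.9)` for D10/D90.
#' @return Named numeric vector of diameters in nm (names `D10` etc.).
#' @export
percentile_diameters <- function(d, q = c(0.1, 0.5, 0.9)) {
  stopifnot(all(q > 0 & q < 1))
  dat <- single_replicate(d)
  total <- sum(dat$concentration)
  if (total <= 0) stop("empty distribution")
  cum_hi <- cumsum(dat$concentration)
  cum_lo <- c(0, cum_hi[-length(cum_hi)])
  lo_edge <- dat$bin_center_nm - 2.5
  out <- vapply(q, function(p) {
    target <- p * total
    i <- which(cum_hi >= target)[1]
    within <- (target - cum_lo[i]) / dat$concentration[i]
    lo_edge[i] + 5 * within
  }, numeric(1))
  names(out) <- paste0("D", round(100 * q))
  out
}

#' Fraction of particle mass above a diameter threshold
#'
#' Bins are counted continuously: a bin straddling the threshold
#' contributes the proportion of its 5-nm width above it.
#'
#' @param d A single-replicate [size_distribution()].
#' @param threshold_nm Diameter threshold in nm.
#' @return Percentage of total mass above the threshold.
#' @export
size_band_fraction <- function(d, threshold_nm) {
  dat <- single_replicate(d)
  lo <- dat$bin_center_nm - 2.5
  hi <- dat$bin_center_nm + 2.5
  frac_above <- pmin(1, pmax(0, (hi - threshold_nm) / 5))
  100 * sum(dat$concentration * frac_above) / sum(dat$concentration)
}
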