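#' Fraction group for a density fraction
#'
#' Density-gradient fractions are analysed in three groups: fractions 1-3
#' (lightest, microvesicle-like), 4-6 (exosome-like) and 7-8 (densest,
#' mitochondria-related vesicles).
#'
#' @param fraction Integer vector of fraction numbers (1-8).
#' @return Factor with levels `"F1-3"`, `"F4-6"`, `"F7-8"`.
#' @export
fraction_group <- function(fraction) {
  fraction <- as.integer(fraction)
  if (any(is.na(fraction)) || any(fraction < 1L | fraction > 8L)) {
    stop("fractions must be integers in 1..8")
  }
  grp <- ifelse(fraction <= 3L, "F1-3", ifelse(fraction <= 6L, "F4-6", "F7-8"))
  factor(grp, levels = c("F1-3", "F4-6", "F7-8"))
}

#' Build a donor-by-fraction sample design
#'
#' One sample per donor and density fraction, named `<donor>_F<fraction>`.
#' By default three donors are excluded from fraction 8 (too little material
#' was recovered for them), giving 8 donors for fractions 1-7 and 5 donors
#' for fraction 8, i.e. 61 samples.
#'
#' @param donors Character vector of donor ids.
#' @param fractions Integer vector of density fractions (subset of 1..8).
#' @param exclude Data frame with columns `donor` and `fraction` listing
#'   donor-fraction combinations to drop.
#' @return Data frame with columns `sample`, `donor`, `fraction`, `group`.
#' @export
make_design <- function(donors = LETTERS[1:8], fractions = 1:8,
                        exclude = data.frame(donor = c("A", "E", "F"),
                                             fraction = 8L)) {
  des <- expand.grid(donor = donors, fraction = as.integer(fractions),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  des <- des[order(des$fraction, match(des$donor, donors)), ]
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop <- paste(des$donor, des$fraction) %in%
      paste(exclude$donor, as.integer(exclude$fraction))
    des <- des[!drop, ]
  }
  des$sample <- paste0(des$donor, "_F", des$fraction)
  des$group <- fraction_group(des$fraction)
  rownames(des) <- NULL
  des[, c("sample", "donor", "fraction", "group")]
}

#' Log2 LFQ intensity matrix with sample design
#'
#' Light container for a proteins/peptides x samples matrix of log2
#' label-free quantification intensities. Missing values are `NA`; the
#' design maps each column to a donor, density fraction and fraction group.
#'
#' @param values Numeric matrix, rows named by accession, columns by sample.
#' @param design Sample design as returned by [make_design()].
#' @param normalized Logical flag; `TRUE` once intensities are on a
#'   normalized scale.
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(values, design, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have row names (accessions)")
  if (anyDuplicated(rownames(values))) stop("duplicate accessions in values")
  if (is.null(colnames(values))) stop("values must have column names (samples)")
  missing_in_design <- setdiff(colnames(values), design$sample)
  missing_in_values <- setdiff(design$sample, colnames(values))
  if (length(missing_in_design) || length(missing_in_values)) {
    stop("design/sample mismatch; not in design: ",
         paste(missing_in_design, collapse = ", "),
         "; not in matrix: ", paste(missing_in_values, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design,
                 normalized = isTRUE(normalized)),
            class = "lfq_matrix")
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("lfq_matrix: %d features x %d samples (%.1f%% missing%s)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Read an LFQ intensity table
#'
#' Reads a tab-separated table whose first column holds accessions and whose
#' remaining columns hold per-sample intensities. Zeros, empty cells and
#' `NaN` are all treated as missing (DIA software dialects differ).
#'
#' @param path Path to the TSV file.
#' @param design Sample design; the table's sample columns must match
#'   `design$sample` exactly (any order).
#' @param log2_transform If `TRUE` the values are raw-scale intensities and
#'   are log2-transformed on import.
#' @return An [lfq_matrix()].
#' @export
read_lfq_table <- function(path, design, log2_transform = FALSE) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("empty or malformed LFQ table: ", path)
  acc <- as.character(tab[[1]])
  if (anyDuplicated(acc)) {
    stop("duplicate accessions in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- acc
  vals[!is.finite(vals) | vals == 0] <- NA_real_
  if (log2_transform) vals <- log2(vals)
  lfq_matrix(vals, design)
}

#' Write an LFQ intensity table
#'
#' Inverse of [read_lfq_table()]: first column `accession`, one column per
#' sample, missing cells written as `NA`.
#'
#' @param m An [lfq_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfq_table <- function(m, path) {
  out <- data.frame(accession = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

values_of <- function(m) if (inherits(m, "lfq_matrix")) m$values else as.matrix(m)
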