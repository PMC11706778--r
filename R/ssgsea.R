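#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member ids. Duplicate ids within a set are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, class `gene_set_collection`,
#'   with descriptions in `attr(, "description")` and the path in
#'   `attr(, "provenance")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with no members: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  structure(sets,
            description = setNames(vapply(parts, `[[`, "", 2), names(sets)),
            provenance = path,
            class = "gene_set_collection")
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character id vectors.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (any(lengths(sets) == 0)) stop("empty gene set(s): ",
                                    paste(names(sets)[lengths(sets) == 0],
                                          collapse = ", "))
  structure(lapply(sets, unique), class = "gene_set_collection")
}

#' Filter gene sets for testing
#'
#' Applies, in order: (1) keep sets with between `min_detected` and
#' `max_detected` members among the detected ids; (2) drop sets whose names
#' match a directionality pattern ("upregulation of" and the like); (3)
#' among pairs whose overlap coefficient `|A&B| / min(|A|,|B|)` (on detected
#' members) exceeds `max_overlap`, keep the higher-priority set. Priority is
#' a named numeric vector (smaller = keep first, e.g. moderated-F p-values);
#' without one, larger sets win. Elimination is greedy in priority order.
#'
#' @param sets A `gene_set_collection` (or named list).
#' @param detected_ids Row ids of the expression matrix.
#' @param min_detected,max_detected Detected-size bounds (defaults 5 and 50).
#' @param max_overlap Overlap-coefficient threshold (default 0.25).
#' @param name_patterns Regex-free substrings flagging directional sets.
#' @param priority Optional named numeric vector; smaller values are kept
#'   preferentially in overlap elimination.
#' @return Filtered `gene_set_collection` with members intersected with
#'   `detected_ids`.
#' @export
filter_gene_sets <- function(sets, detected_ids, min_detected = 5,
                             max_detected = 50, max_overlap = 0.25,
                             name_patterns = c("upregulation of",
                                               "downregulation of",
                                               "positive regulation of",
                                               "negative regulation of"),
                             priority = NULL) {
  detected <- lapply(sets, function(s) intersect(s, detected_ids))
  sz <- lengths(detected)
  keep <- sz >= min_detected & sz <= max_detected
  if (length(name_patterns)) {
    directional <- Reduce(`|`, lapply(name_patterns, function(p)
      grepl(p, names(detected), ignore.case = TRUE, fixed = FALSE)))
    keep <- keep & !directional
  }
  detected <- detected[keep]
  if (length(detected) > 1 && is.finite(max_overlap)) {
    nm <- names(detected)
    rank_key <- if (!is.null(priority)) {
      pr <- priority[nm]
      pr[is.na(pr)] <- Inf
      order(pr, -lengths(detected), nm)
    } else {
      order(-lengths(detected), nm)
    }
    kept <- character(0)
    for (i in rank_key) {
      cand <- detected[[i]]
      ok <- TRUE
      for (kn in kept) {
        ov <- length(intersect(cand, detected[[kn]])) /
          min(length(cand), length(detected[[kn]]))
        if (ov > max_overlap) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, nm[i])
    }
    detected <- detected[nm[nm %in% kept]]
  }
  structure(detected, class = "gene_set_collection")
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ties) and each
#' set scored as the running sum of the difference between the rank-weighted
#' in-set ECDF (weights `rank^alpha`) and the unweighted out-of-set ECDF,
#' walking genes from highest to lowest rank. With `normalize = TRUE` all
#' scores are divided by the range (max - min) over the whole matrix.
#' Scores depend on ranks only, so any monotone per-sample transform of the
#' expression values leaves them unchanged.
#'
#' @param m An [lfq_matrix()] or plain matrix (rows = genes/proteins).
#' @param sets A `gene_set_collection`, already filtered.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide by the overall score range (default `TRUE`).
#' @return Matrix of class `enrichment_matrix`, sets x samples, with
#'   `attr(, "scaled") = FALSE`.
#' @export
ssgsea_scores <- function(m, sets, alpha = 0.25, normalize = TRUE) {
  x <- values_of(m)
  if (anyNA(x)) stop("expression matrix must be complete (impute first)")
  empty <- vapply(sets, function(s) length(intersect(s, rownames(x))) == 0,
                  TRUE)
  if (any(empty)) stop("gene set(s) with no member in the matrix: ",
                       paste(names(sets)[empty], collapse = ", "))
  n <- nrow(x)
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    rnk <- rank(x[, j], ties.method = "average")
    ord <- order(rnk, decreasing = TRUE)
    rnk_ord <- rnk[ord]
    ids_ord <- rownames(x)[ord]
    for (si in seq_along(sets)) {
      inset <- ids_ord %in% sets[[si]]
      w <- rnk_ord^alpha * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (n - sum(inset))
      scores[si, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, scaled = FALSE, class = c("enrichment_matrix", "matrix"))
}

#' Row-scale an enrichment matrix for display
#'
#' Z-scales each gene set's scores across samples (mean 0, SD 1), the
#' convention used for enrichment heat maps.
#'
#' @param E An `enrichment_matrix`.
#' @return The scaled matrix, `attr(, "scaled") = TRUE`.
#' @export
scale_enrichment <- function(E) {
  sds <- apply(E, 1, sd)
  if (any(sds == 0)) stop("constant enrichment row(s): ",
                          paste(rownames(E)[sds == 0], collapse = ", "))
  out <- (E - rowMeans(E)) / sds
  structure(out, scaled = TRUE, class = c("enrichment_matrix", "matrix"))
}

#' Moderated contrasts on ssGSEA scores
#'
#' Applies the same moderated F/t pipeline used for proteins to an
#' enrichment matrix, at the stricter default threshold used for gene sets.
#'
#' @param E An `enrichment_matrix` (sets x samples).
#' @param design Sample design matching the columns of `E`.
#' @param alpha BH-adjusted significance threshold (default 5e-4).
#' @return A `contrast_result` data frame (see [run_contrasts()]).
#' @export
run_ssgsea_contrasts <- function(E, design, alpha = 5e-4) {
  m <- lfq_matrix(unclass(E), design, normalized = TRUE)
  run_contrasts(m, alpha = alpha)
}
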