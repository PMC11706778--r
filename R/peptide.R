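#' Mutual uniqueness of two peptide spans
#'
#' The uniqueness of peptide `b` with respect to `a` is the fraction of
#' `b`'s residues not covered by `a`. The symmetric value used by the
#' merging rule is the minimum of the two directions: identical spans give
#' 0, disjoint spans give 1.
#'
#' @param a_start,a_end,b_start,b_end 1-based inclusive residue coordinates.
#' @return Numeric in \[0, 1\].
#' @export
peptide_uniqueness <- function(a_start, a_end, b_start, b_end) {
  stopifnot(a_start <= a_end, b_start <= b_end)
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  len_a <- a_end - a_start + 1
  len_b <- b_end - b_start + 1
  pmin((len_b - ov) / len_b, (len_a - ov) / len_a)
}

#' Merge near-duplicate peptides into coverage groups
#'
#' Peptides (missed-cleavage and modified variants of the same site) are
#' sorted N to C terminus (by start, then end) and walked in order: a
#' peptide joins the current group when its mutual uniqueness with the
#' group's first (anchor) peptide is at most 0.5; a peptide more than 50%
#' unique from that neighbour starts a new group. Group intensities are the
#' sums of the member intensities on the linear scale, reported as log2.
#'
#' @param peptides Data frame with columns `start`, `end`, optionally
#'   `peptide` and `flag`, plus one log2-intensity column per sample.
#' @param sample_cols Character vector naming the intensity columns;
#'   defaults to every numeric column other than `start`/`end`.
#' @param max_shared Uniqueness threshold at or below which neighbours merge
#'   (default 0.5).
#' @return Data frame of class `peptide_track`: `group`, `start`, `end`,
#'   `n_peptides`, `members`, then one summed log2 intensity column per
#'   sample, ordered by start.
#' @export
merge_near_duplicates <- function(peptides, sample_cols = NULL,
                                  max_shared = 0.5) {
  stopifnot(all(c("start", "end") %in% names(peptides)))
  if (any(peptides$start > peptides$end) || any(peptides$start < 1)) {
    stop("invalid peptide spans")
  }
  if (is.null(sample_cols)) {
    num <- vapply(peptides, is.numeric, TRUE)
    sample_cols <- setdiff(names(peptides)[num], c("start", "end"))
  }
  if (nrow(peptides) == 0) {
    out <- data.frame(group = integer(0), start = integer(0), end = integer(0),
                      n_peptides = integer(0), members = character(0))
    for (s in sample_cols) out[[s]] <- numeric(0)
    class(out) <- c("peptide_track", "data.frame")
    return(out)
  }
  ord <- order(peptides$start, peptides$end)
  p <- peptides[ord, , drop = FALSE]
  gid <- integer(nrow(p))
  gid[1] <- 1L
  anchor <- 1L
  if (nrow(p) > 1) {
    for (i in 2:nrow(p)) {
      u <- peptide_uniqueness(p$start[anchor], p$end[anchor],
                              p$start[i], p$end[i])
      if (u <= max_shared) {
        gid[i] <- gid[i - 1]
      } else {
        gid[i] <- gid[i - 1] + 1L
        anchor <- i
      }
    }
  }
  member_col <- if ("peptide" %in% names(p)) p$peptide else
    paste0(p$start, "-", p$end)
  groups <- split(seq_len(nrow(p)), gid)
  rows <- lapply(groups, function(ix) {
    lin <- vapply(sample_cols,
                  function(s) sum(2^p[[s]][ix]), numeric(1))
    cbind(data.frame(group = gid[ix[1]],
                     start = min(p$start[ix]), end = max(p$end[ix]),
                     n_peptides = length(ix),
                     members = paste(member_col[ix], collapse = ";"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(log2(lin)), col.names = sample_cols,
                        check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peptide_track", "data.frame")
  out
}

#' Default 2N4R tau region annotations
#'
#' Printed landmark regions on the 441-residue 2N4R tau numbering: the
#' extreme N terminus, the four-repeat region, and the Tau13, HT7 and TauC
#' antibody epitopes.
#'
#' @return Data frame `name`, `start`, `end`.
#' @export
tau_regions <- function() {
  data.frame(
    name = c("extreme N terminus", "repeat region",
             "Tau13 epitope", "HT7 epitope", "TauC epitope"),
    start = c(6L, 242L, 2L, 159L, 242L),
    end = c(23L, 370L, 18L, 163L, 411L),
    stringsAsFactors = FALSE)
}

#' Annotate peptide groups with overlapping regions
#'
#' Labels each group of a [merge_near_duplicates()] track with every region
#' it overlaps (1-based inclusive coordinates).
#'
#' @param track A `peptide_track`.
#' @param regions Data frame `name`, `start`, `end`; defaults to
#'   [tau_regions()].
#' @return The track with an added `regions` column (semicolon-separated
#'   names, empty when no region overlaps).
#' @export
annotate_regions <- function(track, regions = tau_regions()) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  track$regions <- vapply(seq_len(nrow(track)), function(i) {
    hit <- regions$start <= track$end[i] & regions$end >= track$start[i]
    paste(regions$name[hit], collapse = ";")
  }, "")
  track
}
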