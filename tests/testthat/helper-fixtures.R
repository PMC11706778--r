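# Small designs and studies shared across test files.

# one sample per group triple (fractions 1, 4, 7) per donor
tiny_design <- function(n_donors = 4, fractions = c(1L, 4L, 7L)) {
  make_design(LETTERS[seq_len(n_donors)], fractions, exclude = NULL)
}

toy_lfq <- function(values, design, normalized = TRUE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  }
  colnames(values) <- design$sample
  lfq_matrix(values, design, normalized = normalized)
}

# down-scaled study exercising the same code path as the full design
reduced_config <- function(seed = 7L, n_proteins = 1000, n_dep = 300, ...) {
  sim_config(n_proteins = n_proteins, n_dep = n_dep, seed = seed, ...)
}

# permute protein rows of a simulated study, keeping all parts aligned
permute_study_rows <- function(study, perm) {
  study$complete$values <- study$complete$values[perm, , drop = FALSE]
  study$observed$values <- study$observed$values[perm, , drop = FALSE]
  study$missingness <- study$missingness[perm, , drop = FALSE]
  study$dep <- study$dep[perm, , drop = FALSE]
  study
}
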