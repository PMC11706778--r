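#' Configuration for a synthetic fractionation study
#'
#' Describes the statistical structure of a simulated density-fractionation
#' LFQ study: per-protein intensity moments, planted differentially enriched
#' proteins (DEPs) with a group-specific log2 shift, and a two-mechanism
#' missingness model (intensity-censored MNAR plus protein-clustered MAR).
#'
#' Defaults reproduce the scale of the reference design: 6,105 proteins over
#' 8 donors x fractions 1-7 plus 5 donors x fraction 8 (61 samples), with
#' 3,000 planted DEPs. The free parameters of the missingness and effect-size
#' models (rates, censor quantile, clustering fraction) are calibrated so
#' that the simulation behaves like the real data the pipeline was designed
#' for; the methods vignette documents the calibration.
#'
#' @param n_proteins Number of protein rows.
#' @param n_donors Donors for fractions 1-7.
#' @param fractions Density fractions simulated.
#' @param n_donors_fraction8 Donors retained in fraction 8.
#' @param n_dep Number of planted DEPs.
#' @param dep_effect_mean,dep_effect_sd The per-DEP log2 shift is
#'   `sign * abs(rnorm(1, dep_effect_mean, dep_effect_sd))` with random sign,
#'   applied in one randomly chosen fraction group.
#' @param protein_mean_mean,protein_mean_sd Hyperparameters of the
#'   per-protein mean log2 intensity (normal law).
#' @param protein_sd_mean,protein_sd_sd,protein_sd_min Per-protein
#'   within-group SD is `max(protein_sd_min, rnorm(mean, sd))` (log2 units).
#' @param mnar_rate Fraction of all cells censored as MNAR.
#' @param mar_rate Fraction of all cells removed as MAR.
#' @param mnar_censor_quantile Intensity quantile of the complete matrix
#'   below which MNAR censoring applies; must be >= `mnar_rate`.
#' @param mnar_steepness Scale (log2 units) of the logistic censoring weight
#'   below the threshold; smaller values censor the lowest intensities first.
#' @param mar_protein_frac Fraction of proteins carrying MAR cells; MAR
#'   missingness clusters in this subset (proteins missing values from a
#'   small number of donors), the rest stay MAR-free.
#' @param mar_margin MAR-carrying proteins are drawn from those whose true
#'   mean lies at least this many log2 units above the MNAR censor
#'   threshold: random dropout happens among quantified proteins, while
#'   below-detection proteins are censored instead.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 6105, n_donors = 8, fractions = 1:8,
                       n_donors_fraction8 = 5, n_dep = 3000,
                       dep_effect_mean = 2.0, dep_effect_sd = 0.3,
                       protein_mean_mean = 11.8, protein_mean_sd = 1.1,
                       protein_sd_mean = 0.25, protein_sd_sd = 0.05,
                       protein_sd_min = 0.15,
                       mnar_rate = 0.135, mar_rate = 0.09,
                       mnar_censor_quantile = 0.14, mnar_steepness = 0.4,
                       mar_protein_frac = 0.40, mar_margin = 0.5,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_donors = as.integer(n_donors),
              fractions = as.integer(fractions),
              n_donors_fraction8 = as.integer(n_donors_fraction8),
              n_dep = as.integer(n_dep),
              dep_effect_mean = dep_effect_mean,
              dep_effect_sd = dep_effect_sd,
              protein_mean_mean = protein_mean_mean,
              protein_mean_sd = protein_mean_sd,
              protein_sd_mean = protein_sd_mean,
              protein_sd_sd = protein_sd_sd,
              protein_sd_min = protein_sd_min,
              mnar_rate = mnar_rate, mar_rate = mar_rate,
              mnar_censor_quantile = mnar_censor_quantile,
              mnar_steepness = mnar_steepness,
              mar_protein_frac = mar_protein_frac,
              mar_margin = mar_margin,
              seed = as.integer(seed))
  if (cfg$n_dep > cfg$n_proteins) stop("n_dep must not exceed n_proteins")
  rates <- c(cfg$mnar_rate, cfg$mar_rate, cfg$mnar_censor_quantile,
             cfg$mar_protein_frac)
  if (any(rates < 0 | rates > 1)) stop("rates and quantiles must be in [0, 1]")
  if (cfg$mnar_rate + cfg$mar_rate > 0.95) {
    stop("mnar_rate + mar_rate > 0.95: matrix would be unusably sparse")
  }
  if (cfg$mnar_rate > cfg$mnar_censor_quantile) {
    stop("mnar_rate exceeds mnar_censor_quantile: not enough cells below ",
         "the censor threshold")
  }
  if (8L %in% cfg$fractions && cfg$n_donors_fraction8 > cfg$n_donors) {
    stop("n_donors_fraction8 must not exceed n_donors")
  }
  structure(cfg, class = "sim_config")
}

design_from_config <- function(config) {
  donors <- LETTERS[seq_len(config$n_donors)]
  exclude <- NULL
  if (8L %in% config$fractions && config$n_donors_fraction8 < config$n_donors) {
    n_drop <- config$n_donors - config$n_donors_fraction8
    # mirror the real exclusions (donors A, E, F) where the default 8-donor
    # naming applies, otherwise drop from the end
    drop_donors <- if (config$n_donors == 8L && n_drop == 3L) c("A", "E", "F")
                   else rev(donors)[seq_len(n_drop)]
    exclude <- data.frame(donor = drop_donors, fraction = 8L)
  }
  make_design(donors, config$fractions, exclude)
}

#' Simulate a complete (no missing values) study
#'
#' Draws per-protein means and SDs from the configured hyperpriors, samples
#' every cell from the protein's normal law, and adds each planted DEP's
#' log2 shift to all samples of its target fraction group.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulated_study` with elements `complete`
#'   (an [lfq_matrix()]), `dep` (per-protein truth table: `is_dep`,
#'   `dep_group`, `dep_effect`), `config`; `observed` and `missingness`
#'   are `NULL` until [inject_missingness()] is applied.
#' @export
simulate_complete_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  des <- design_from_config(config)
  n <- config$n_proteins
  p_mean <- rnorm(n, config$protein_mean_mean, config$protein_mean_sd)
  p_sd <- pmax(config$protein_sd_min,
               rnorm(n, config$protein_sd_mean, config$protein_sd_sd))
  acc <- sprintf("P%05d", seq_len(n))
  dep_idx <- sort(sample.int(n, config$n_dep))
  dep_group <- factor(sample(levels(des$group), config$n_dep, replace = TRUE),
                      levels = levels(des$group))
  dep_effect <- sample(c(-1, 1), config$n_dep, replace = TRUE) *
    abs(rnorm(config$n_dep, config$dep_effect_mean, config$dep_effect_sd))
  m <- matrix(rnorm(n * nrow(des)), nrow = n) * p_sd + p_mean
  rownames(m) <- acc
  colnames(m) <- des$sample
  for (g in levels(des$group)) {
    rows <- dep_idx[dep_group == g]
    cols <- des$group == g
    m[rows, cols] <- m[rows, cols] + dep_effect[dep_group == g]
  }
  dep <- data.frame(protein = acc, is_dep = FALSE,
                    dep_group = factor(NA, levels = levels(des$group)),
                    dep_effect = NA_real_, stringsAsFactors = FALSE)
  dep$is_dep[dep_idx] <- TRUE
  dep$dep_group[dep_idx] <- dep_group
  dep$dep_effect[dep_idx] <- dep_effect
  structure(list(complete = lfq_matrix(m, des, normalized = TRUE),
                 observed = NULL, dep = dep, missingness = NULL,
                 config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d proteins x %d samples, %d DEPs%s\n",
              nrow(x$complete$values), ncol(x$complete$values),
              sum(x$dep$is_dep),
              if (is.null(x$observed)) " (complete)" else
                sprintf(", %.1f%% missing", 100 * mean(is.na(x$observed$values)))))
  invisible(x)
}

#' Inject MNAR and MAR missingness into a simulated study
#'
#' MNAR cells are drawn without replacement from the cells below the censor
#' threshold (the `mnar_censor_quantile` of all intensities), with logistic
#' weight increasing as intensity falls, until `mnar_rate` of all cells are
#' censored. MAR cells are then drawn uniformly from the remaining cells of
#' a random `mar_protein_frac` subset of proteins until `mar_rate` of all
#' cells are removed. Every missing cell gets exactly one truth label.
#'
#' @param study A `simulated_study` from [simulate_complete_matrix()].
#' @param config Optional [sim_config()] overriding `study$config`.
#' @return The study with `observed` (values `NA` where missing) and
#'   `missingness` (character matrix, `"observed"`/`"MNAR"`/`"MAR"`) filled.
#' @export
inject_missingness <- function(study, config = study$config) {
  stopifnot(inherits(study, "simulated_study"))
  m <- study$complete$values
  n_cells <- length(m)
  set.seed(config$seed + 1L)
  lab <- matrix("observed", nrow(m), ncol(m), dimnames = dimnames(m))
  n_mnar <- round(config$mnar_rate * n_cells)
  n_mar <- round(config$mar_rate * n_cells)
  if (n_mnar > 0) {
    x0 <- quantile(m, config$mnar_censor_quantile, names = FALSE)
    pool <- which(m < x0)
    w <- plogis((x0 - m[pool]) / config$mnar_steepness)
    # weighted sampling without replacement via exponential races
    keys <- rexp(length(pool)) / w
    mnar_idx <- pool[order(keys)[seq_len(min(n_mnar, length(pool)))]]
    lab[mnar_idx] <- "MNAR"
  }
  if (n_mar > 0) {
    n_mar_prot <- max(1L, round(config$mar_protein_frac * nrow(m)))
    x0 <- quantile(m, config$mnar_censor_quantile, names = FALSE)
    eligible <- which(rowMeans(m) >= x0 + config$mar_margin)
    if (length(eligible) < n_mar_prot) eligible <- seq_len(nrow(m))
    mar_rows <- eligible[sample.int(length(eligible),
                                    min(n_mar_prot, length(eligible)))]
    cand <- which(lab == "observed" & row(m) %in% mar_rows)
    mar_idx <- sample(cand, min(n_mar, length(cand)))
    lab[mar_idx] <- "MAR"
  }
  obs <- m
  obs[lab != "observed"] <- NA_real_
  study$observed <- lfq_matrix(obs, study$complete$design, normalized = TRUE)
  study$missingness <- lab
  study
}

#' Simulate a study (complete matrix plus missingness)
#'
#' Convenience composition of [simulate_complete_matrix()] and
#' [inject_missingness()].
#'
#' @inheritParams simulate_complete_matrix
#' @return A `simulated_study` with observed matrix and truth labels.
#' @export
simulate_study <- function(config = sim_config()) {
  inject_missingness(simulate_complete_matrix(config))
}

#' Simulate a tau-like peptide table
#'
#' Generates tryptic-style peptides along a protein of given length
#' (default 441 residues, the longest 2N4R tau isoform), including
#' missed-cleavage / modified near-duplicates that extend or share spans,
#' with per-sample log2 intensities. Fixture generator for the peptide
#' coverage track.
#'
#' @param n_peptides Number of peptides.
#' @param protein_length Protein length in residues (default 441).
#' @param samples Character vector of sample names.
#' @param duplicate_frac Fraction of peptides emitted as near-duplicates of
#'   an earlier peptide (extended span, flagged).
#' @param seed Integer seed.
#' @return Data frame: `peptide`, `start`, `end`, `flag`
#'   (`""`/`"missed_cleavage"`/`"modified"`), one log2-intensity column per
#'   sample.
#' @export
simulate_peptide_table <- function(n_peptides, protein_length = 441,
                                   samples = paste0("S", 1:4),
                                   duplicate_frac = 0.3, seed = 1L) {
  set.seed(seed)
  cols <- c("peptide", "start", "end", "flag", samples)
  if (n_peptides == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    out$start <- integer(0); out$end <- integer(0)
    for (s in samples) out[[s]] <- numeric(0)
    return(out)
  }
  n_dup <- if (n_peptides > 1) rbinom(1, n_peptides - 1, duplicate_frac) else 0L
  n_base <- n_peptides - n_dup
  start <- sample.int(protein_length - 7L, n_base, replace = TRUE)
  len <- pmin(sample(7:25, n_base, replace = TRUE), protein_length - start + 1L)
  end <- start + len - 1L
  flag <- rep("", n_base)
  if (n_dup > 0) {
    src <- sample.int(n_base, n_dup, replace = TRUE)
    d_start <- start[src]
    d_end <- pmin(protein_length, end[src] + sample(0:6, n_dup, replace = TRUE))
    start <- c(start, d_start); end <- c(end, d_end)
    flag <- c(flag, sample(c("missed_cleavage", "modified"), n_dup,
                           replace = TRUE))
  }
  stopifnot(all(start >= 1), all(end <= protein_length))
  base_int <- rnorm(length(start), 20, 2)
  ints <- sapply(samples, function(s) base_int + rnorm(length(start), 0, 0.5))
  ints <- matrix(ints, ncol = length(samples),
                 dimnames = list(NULL, samples))
  out <- data.frame(peptide = sprintf("pep%03d", seq_along(start)),
                    start = as.integer(start), end = as.integer(end),
                    flag = flag, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ints))
}

#' Simulate raw NTA size-distribution exports
#'
#' Draws particle diameters from a size law, bins them on the instrument's
#' 5-nm grid (bin centers at multiples of 5 nm) and reports per-replicate
#' diluted concentrations. Fixture generator for the NTA module.
#'
#' @param n_particles Particles tracked per technical replicate.
#' @param dist Size law: `"lognormal"` (parameters `meanlog`, `sdlog` of the
#'   diameter in nm), `"uniform"` (`min`, `max`) or `"point"` (`at`).
#' @param meanlog,sdlog,min,max,at Distribution parameters.
#' @param dilution Dilution factor (>= 1); reported concentrations are
#'   counts divided by it, as the instrument sees the diluted sample.
#' @param replicates Number of technical replicates.
#' @param seed Integer seed.
#' @return A [size_distribution()] with one block per replicate and the
#'   dilution factor recorded.
#' @export
simulate_nta_readings <- function(n_particles = 10000, dist = "lognormal",
                                  meanlog = log(130), sdlog = 0.35,
                                  min = 50, max = 300, at = 130,
                                  dilution = 1000, replicates = 3, seed = 1L) {
  if (dilution <= 0) stop("dilution factor must be positive")
  set.seed(seed)
  blocks <- lapply(seq_len(replicates), function(r) {
    d <- switch(dist,
                lognormal = rlnorm(n_particles, meanlog, sdlog),
                uniform = runif(n_particles, min, max),
                point = rep(at, n_particles),
                stop("unknown size law: ", dist))
    bin <- round(d / 5) * 5
    tab <- table(bin)
    data.frame(bin_center_nm = as.numeric(names(tab)),
               concentration = as.numeric(tab) / dilution,
               replicate = r)
  })
  grid <- sort(unique(unlist(lapply(blocks, `[[`, "bin_center_nm"))))
  blocks <- lapply(blocks, function(b) {
    conc <- setNames(rep(0, length(grid)), grid)
    conc[as.character(b$bin_center_nm)] <- b$concentration
    data.frame(bin_center_nm = grid, concentration = as.numeric(conc),
               replicate = b$replicate[1])
  })
  size_distribution(do.call(rbind, blocks), dilution = dilution)
}

#' Write a simulated study to plain-text files
#'
#' Writes the observed and complete matrices as TSV (first column
#' `accession`, sample columns `<donor>_F<fraction>`), the DEP and
#' missingness truth tables as TSV, and a YAML echo of the configuration.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lfq_table(study$complete, file.path(dir, "complete.tsv"))
  if (!is.null(study$observed)) {
    write_lfq_table(study$observed, file.path(dir, "observed.tsv"))
    miss <- data.frame(accession = rownames(study$missingness),
                       study$missingness, check.names = FALSE)
    write.table(miss, file.path(dir, "missingness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(study$dep, file.path(dir, "dep_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(study$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
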