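#' Per-protein cell-means fit across the three fraction groups
#'
#' Ordinary least squares with one mean per fraction group (F1-3, F4-6,
#' F7-8). Rows may contain missing values: a row is `tested` only if every
#' group has at least `min_per_group` observed values; untested rows carry
#' `NA` statistics. For a complete matrix the residual degrees of freedom
#' are `n - 3`.
#'
#' @param m An [lfq_matrix()].
#' @param min_per_group Minimum observed values per group (default 2).
#' @return Object of class `group_fit`: per-protein group means `means`,
#'   group sizes `n`, residual variance `s2`, residual df `df`, logical
#'   `tested`, plus the group levels.
#' @export
fit_group_model <- function(m, min_per_group = 2) {
  stopifnot(inherits(m, "lfq_matrix"))
  vals <- m$values
  grp <- m$design$group
  lev <- levels(grp)
  if (length(lev) != 3) stop("design must carry the three fraction groups")
  means <- ns <- matrix(NA_real_, nrow(vals), length(lev),
                        dimnames = list(rownames(vals), lev))
  rss <- rep(0, nrow(vals))
  for (g in seq_along(lev)) {
    sub <- vals[, grp == lev[g], drop = FALSE]
    ns[, g] <- rowSums(!is.na(sub))
    means[, g] <- rowMeans(sub, na.rm = TRUE)
    dev <- sub - means[, g]
    rss <- rss + rowSums(dev^2, na.rm = TRUE)
  }
  tested <- rowSums(ns >= min_per_group) == length(lev)
  df <- rowSums(ns) - length(lev)
  s2 <- ifelse(df > 0, rss / df, NA_real_)
  means[ns == 0] <- NA_real_
  s2[!tested] <- NA_real_
  df[!tested] <- NA_real_
  structure(list(means = means, n = ns, s2 = s2, df = df, tested = tested,
                 groups = lev),
            class = "group_fit")
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[y <= 0] <- Inf
  todo <- which(is.finite(y) & y > 0)
  if (!length(todo)) return(out)
  yy <- y[todo]
  x <- 0.5 + 1 / yy
  for (it in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  out[todo] <- x
  out
}

#' Empirical Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-squared prior (`d0`, `s0^2`) to the per-protein
#' residual variances by moment matching on the log scale, then shrinks each
#' variance to its posterior `(d0 s0^2 + df s^2) / (d0 + df)` and forms
#' moderated t statistics for the three pairwise group contrasts and a
#' moderated F across the groups, with `d0 + df` denominator degrees of
#' freedom (capped at the pooled residual df).
#'
#' Variances exactly zero (constant rows) are excluded from hyperparameter
#' estimation; if all usable log-variances are equally dispersed or less
#' than sampling noise predicts, the prior df is infinite and every
#' posterior variance equals `s0^2`.
#'
#' @param fit A `group_fit` from [fit_group_model()].
#' @param prior_df,prior_var Optional overrides for `d0` and `s0^2` (use
#'   `prior_df = 0` to recover ordinary statistics, `prior_df = Inf` for
#'   complete pooling).
#' @return Object of class `moderated_fit`: the fit plus `d0`, `s02`,
#'   `s2_post`, `df_total`, contrast log2 fold changes `lfc`, moderated `t`
#'   and p-values `p_t`, moderated `F` and `p_F`.
#' @export
ebayes_moderate <- function(fit, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(fit, "group_fit"))
  s2 <- fit$s2
  df <- fit$df
  usable <- fit$tested & is.finite(s2) & s2 > 0 & df > 0
  if (is.null(prior_df) || is.null(prior_var)) {
    if (sum(usable) < 10) {
      stop("need >= 10 proteins with positive residual variance to ",
           "estimate the variance prior")
    }
    z <- log(s2[usable])
    e <- z - digamma(df[usable] / 2) + log(df[usable] / 2)
    emean <- mean(e)
    evar <- var(e) - mean(trigamma(df[usable] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  }
  if (!is.null(prior_df)) d0 <- prior_df
  if (!is.null(prior_var)) s02 <- prior_var
  df0 <- ifelse(is.na(df), 0, df)
  s2_post <- if (is.finite(d0)) {
    (d0 * s02 + df0 * ifelse(is.na(s2), 0, s2)) / (d0 + df0)
  } else {
    rep(s02, length(s2))
  }
  s2_post[!fit$tested] <- NA_real_
  df_pooled <- sum(df[fit$tested], na.rm = TRUE)
  df_total <- pmin(df + d0, df_pooled)
  lev <- fit$groups
  contrasts <- list(c(2, 1), c(3, 1), c(3, 2))
  cn <- vapply(contrasts, function(ct) paste(lev[ct[1]], "vs", lev[ct[2]]), "")
  lfc <- tmat <- pmat <- matrix(NA_real_, length(s2), length(contrasts),
                                dimnames = list(rownames(fit$means), cn))
  for (j in seq_along(contrasts)) {
    a <- contrasts[[j]][1]; b <- contrasts[[j]][2]
    lfc[, j] <- fit$means[, a] - fit$means[, b]
    se <- sqrt(s2_post * (1 / fit$n[, a] + 1 / fit$n[, b]))
    tmat[, j] <- lfc[, j] / se
    pmat[, j] <- 2 * pt(abs(tmat[, j]), df_total, lower.tail = FALSE)
  }
  ntot <- rowSums(fit$n)
  grand <- rowSums(fit$n * fit$means) / ntot
  ssb <- rowSums(fit$n * (fit$means - grand)^2)
  Fstat <- ssb / ((length(lev) - 1) * s2_post)
  pF <- pf(Fstat, length(lev) - 1, df_total, lower.tail = FALSE)
  Fstat[!fit$tested] <- NA_real_
  pF[!fit$tested] <- NA_real_
  out <- c(fit, list(d0 = d0, s02 = s02, s2_post = s2_post,
                     df_total = df_total, lfc = lfc, t = tmat, p_t = pmat,
                     F = Fstat, p_F = pF))
  class(out) <- c("moderated_fit", "group_fit")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, clamped to 1 and monotone in
#' rank. `NA` p-values (untested proteins) stay `NA` and do not count
#' towards the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential enrichment across the three fraction groups
#'
#' Composition of [fit_group_model()], [ebayes_moderate()] and
#' [bh_adjust()]: per-protein moderated F across F1-3/F4-6/F7-8 plus
#' pairwise moderated t, with significance at BH-adjusted F p-values below
#' `alpha` (no fold-change cutoff).
#'
#' @param m An [lfq_matrix()] (imputed, or with missing values in which case
#'   only proteins with at least `min_per_group` observed values per group
#'   are tested).
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_per_group Passed to [fit_group_model()].
#' @return Data frame of class `contrast_result`, one row per protein:
#'   group means, `logFC_*`, `s2`, `df`, `t_*`, `F`, `p_F`, `adj_p_F`,
#'   `significant`. The moderated fit is attached as `attr(, "fit")`.
#' @export
run_contrasts <- function(m, alpha = 0.05, min_per_group = 2) {
  fit <- ebayes_moderate(fit_group_model(m, min_per_group = min_per_group))
  adj <- bh_adjust(fit$p_F)
  res <- data.frame(protein = rownames(fit$means),
                    fit$means,
                    logFC = fit$lfc, s2 = fit$s2, df = fit$df,
                    t = fit$t, F = fit$F, p_F = fit$p_F, adj_p_F = adj,
                    significant = !is.na(adj) & adj < alpha,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "fit") <- fit
  attr(res, "alpha") <- alpha
  class(res) <- c("contrast_result", "data.frame")
  res
}
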