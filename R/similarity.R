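#' Pearson similarity between human and model condition means
#'
#' The standard product-moment correlation between analogous human and
#' model data points across experimental conditions.
#'
#' @param human,model numeric vectors of equal length (>= 3), finite
#' @return correlation coefficient in `[-1, 1]`
#' @export
pearson_similarity <- function(human, model) {
  stopifnot(length(human) == length(model))
  if (length(human) < 3) stop("need at least 3 paired conditions")
  if (!all(is.finite(human)) || !all(is.finite(model)))
    stop("inputs must be finite")
  if (stats::sd(human) == 0 || stats::sd(model) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(human, model)
}

#' Min-max-normalized RMS error between human and model data
#'
#' Human data are rescaled to range from 0 to 1 across conditions, the same
#' scaling (human-derived offset and scale only) is applied to the model
#' data, and the root-mean-squared difference is returned. With a grouping
#' vector, the min/max are computed per scaling group across all conditions
#' in the group - so an experiment with a null effect, normalized within a
#' shared group, cannot yield an artificially small error.
#'
#' @param human,model numeric vectors of equal length
#' @param shared_scaling_group optional grouping vector (factor-like); the
#'   human min/max are computed within each group
#' @return RMS of normalized human-model differences
#' @export
minmax_rms <- function(human, model, shared_scaling_group = NULL) {
  stopifnot(length(human) == length(model))
  g <- if (is.null(shared_scaling_group)) rep(1L, length(human))
       else shared_scaling_group
  stopifnot(length(g) == length(human))
  hn <- numeric(length(human)); mn <- numeric(length(model))
  for (grp in unique(g)) {
    sel <- g == grp
    lo <- min(human[sel]); hi <- max(human[sel])
    if (hi - lo <= 0)
      stop("flat human data in a scaling group: normalization undefined")
    hn[sel] <- (human[sel] - lo) / (hi - lo)
    mn[sel] <- (model[sel] - lo) / (hi - lo)
  }
  sqrt(mean((hn - mn)^2))
}

#' Bootstrap confidence interval and Gaussian-null p-value
#'
#' Resamples the per-unit scores (e.g. per observer or per network
#' architecture) with replacement `n_boot` times, computing the resampled
#' mean each time. Returns the percentile 95% CI of the mean. When a
#' `null_values` vector is supplied, its bootstrapped means form the null
#' distribution: a Normal is fitted to it and a two-tailed p-value for the
#' observed mean of `values` is read from that Gaussian.
#'
#' @param values per-unit scores (>= 2)
#' @param n_boot number of bootstrap resamples (default 1000)
#' @param seed integer seed
#' @param null_values optional per-unit scores defining the null
#' @return an object of class `similarity_report` with fields `mean`,
#'   `ci95`, `p_two_tailed` (NA without a null), `n_boot`, `seed`
#' @export
bootstrap_stats <- function(values, n_boot = 1000, seed = 1,
                            null_values = NULL) {
  if (length(values) < 2) stop("need at least 2 units")
  old <- local_seed(seed); on.exit(restore_seed(old))
  boots <- replicate(n_boot, mean(sample(values, replace = TRUE)))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  p <- NA_real_
  if (!is.null(null_values)) {
    nb <- replicate(n_boot, mean(sample(null_values, replace = TRUE)))
    mu0 <- mean(nb); sd0 <- stats::sd(nb)
    if (sd0 == 0) {
      p <- if (mean(values) == mu0) 1 else 0
    } else {
      z <- (mean(values) - mu0) / sd0
      p <- 2 * stats::pnorm(-abs(z))
    }
    p <- min(p, 1)
  }
  structure(list(mean = mean(values), ci95 = ci, p_two_tailed = p,
                 n_boot = n_boot, seed = seed, boot_means = boots),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("similarity_report: mean %.4g, 95%% CI [%.4g, %.4g]",
              x$mean, x$ci95[1], x$ci95[2]))
  if (!is.na(x$p_two_tailed)) cat(sprintf(", p = %.3g", x$p_two_tailed))
  cat(sprintf(" (%d bootstrap resamples)\n", x$n_boot))
  invisible(x)
}

#' Noise-corrected explained variance
#'
#' Divides the human-model Pearson r^2 by the product of the human and
#' model split-half reliabilities (each Spearman-Brown corrected,
#' `2r / (1 + r)`), estimating the fraction of explainable variance in the
#' human data accounted for by the model.
#'
#' @param r human-model Pearson correlation of full-data condition means
#' @param human_halves,model_halves two-column matrices (or data.frames),
#'   one column per split half, rows = conditions
#' @return fraction of explainable variance, with attribute `reliabilities`
#' @export
reliability_corrected_r2 <- function(r, human_halves, model_halves) {
  rel <- function(h) {
    h <- as.matrix(h)
    stopifnot(ncol(h) == 2)
    r_half <- stats::cor(h[, 1], h[, 2])
    2 * r_half / (1 + r_half)  # Spearman-Brown
  }
  rel_h <- rel(human_halves); rel_m <- rel(model_halves)
  if (!is.finite(rel_h) || !is.finite(rel_m) || rel_h <= 0 || rel_m <= 0)
    stop("non-positive split-half reliability: correction undefined")
  structure(r^2 / (rel_h * rel_m),
            reliabilities = c(human = rel_h, model = rel_m))
}

# Interaction F-statistic for a 2-level within factor crossed with a
# between factor. With two within levels the interaction reduces to a
# one-way ANOVA on within-unit differences across between-groups.
interaction_F <- function(d, groups) {
  gm <- tapply(d, groups, mean)
  ng <- tapply(d, groups, length)
  grand <- mean(d)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((d - gm[match(groups, names(gm))])^2)
  dfb <- length(gm) - 1L
  dfw <- length(d) - length(gm)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)  # degenerate designs
  (ssb / dfb) / (ssw / dfw)
}

#' Permutation test for a between-by-within interaction
#'
#' Computes an F-statistic for the interaction between a between-units
#' factor (e.g. phase-locking cutoff) and a two-level within-units factor
#' (e.g. reverberation) from a units-by-2 score table, then re-computes it
#' with the within-condition labels permuted independently within each
#' unit (sign flips of the within-unit difference), assembling a null
#' distribution. The p-value is `(1 + #permuted F >= observed F) /
#' (n_perm + 1)`.
#'
#' @param scores matrix or data.frame, one row per unit, exactly 2 columns
#'   (the within-factor levels)
#' @param between_labels between-factor label per unit (length nrow)
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @return list with `F_obs`, `p`, `n_perm`
#' @export
permutation_interaction_test <- function(scores, between_labels,
                                         n_perm = 10000, seed = 1) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2)
    stop("within factor must have exactly 2 levels (2 columns)")
  if (nrow(scores) != length(between_labels))
    stop("one between label per unit required")
  if (length(unique(between_labels)) < 2)
    stop("need >= 2 between-factor groups")
  d <- scores[, 2] - scores[, 1]
  groups <- as.character(between_labels)
  F_obs <- interaction_F(d, groups)
  old <- local_seed(seed); on.exit(restore_seed(old))
  n <- length(d)
  # vectorized sign-flip permutations
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                  nrow = n_perm)
  F_perm <- apply(signs, 1L, function(s) interaction_F(d * s, groups))
  p <- (1 + sum(F_perm >= F_obs)) / (n_perm + 1)
  list(F_obs = F_obs, p = p, n_perm = n_perm)
}
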