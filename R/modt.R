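#' Empirical-Bayes moderated two-group t-test
#'
#' Fits, for every feature (row) of a log2-intensity matrix, the two-group
#' comparison `group_a - group_b` with an empirical-Bayes moderated
#' t-statistic: per-feature residual variances are shrunk toward a prior
#' variance whose value and weight (prior degrees of freedom) are estimated
#' across features by moment matching on the scaled-F distribution of the
#' sample variances. The moderated statistic is
#' \deqn{\tilde t_g = \frac{\bar y_{gA} - \bar y_{gB}}
#'   {\tilde s_g \sqrt{1/n_A + 1/n_B}}, \qquad
#'   \tilde s_g^2 = \frac{d_g s_g^2 + d_0 s_0^2}{d_g + d_0},}
#' with two-sided p-values from a t distribution on \eqn{d_g + d_0} degrees
#' of freedom and Benjamini-Hochberg adjusted p-values appended. With
#' `prior_df = 0` the statistic reduces to the ordinary pooled-variance
#' two-sample t; with `prior_df = Inf` every feature uses the common prior
#' variance.
#'
#' Rows may contain missing values; group means and pooled variances are then
#' computed over the valid entries and the residual degrees of freedom vary
#' by feature. Features with fewer than two valid values in either group get
#' `NA` statistics. A matrix that is constant within both groups yields zero
#' statistics and p-values of 1 rather than an error.
#'
#' @param x numeric matrix of log2 intensities, features in rows, samples in
#'   columns (column names are sample ids).
#' @param design a [sample_design()] covering the columns of `x`, or a
#'   character/factor vector of group labels per column.
#' @param group_a,group_b the two group labels to contrast (`group_a` minus
#'   `group_b`). Both groups must contain at least two samples.
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom (`0` disables moderation, `Inf` fully pools variances).
#' @return an object of class `modt`: a list with the per-feature results
#'   `table` (columns `feature_id`, `log2_fc`, `mean_a`, `mean_b`, `t`,
#'   `p_value`, `adj_p`, `n_valid_a`, `n_valid_b`, `df_total`), the shrinkage
#'   estimate (`prior_df`, `prior_var`, `posterior_var`) and the contrast
#'   metadata. Supports `print`, `summary`, `coef`, `plot` and
#'   `as.data.frame`.
#' @examples
#' m <- matrix(rnorm(600), 100, 6,
#'             dimnames = list(paste0("P", 1:100), paste0("s", 1:6)))
#' m[1:5, 1:3] <- m[1:5, 1:3] + 3
#' fit <- moderated_ttest(m, rep(c("bait", "ctrl"), each = 3), "bait", "ctrl")
#' head(coef(fit))
#' summary(fit)
#' @export
moderated_ttest <- function(x, design, group_a, group_b, prior_df = NULL) {
  if (inherits(x, "quant_table")) {
    if (x$scale != "log2")
      stop("quant_table must be on log2 scale", call. = FALSE)
    x <- x$intensities
  }
  stopifnot(is.matrix(x), is.numeric(x))
  groups <- if (inherits(design, "sample_design"))
    design_groups(design, colnames(x)) else as.character(design)
  if (length(groups) != ncol(x))
    stop("group labels do not match the number of samples", call. = FALSE)
  ia <- which(!is.na(groups) & groups == group_a)
  ib <- which(!is.na(groups) & groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples (", group_a, ": ", length(ia),
         ", ", group_b, ": ", length(ib), ")", call. = FALSE)
  xa <- x[, ia, drop = FALSE]
  xb <- x[, ib, drop = FALSE]
  na <- rowSums(!is.na(xa))
  nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  ssa <- rowSums((xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((xb - mb)^2, na.rm = TRUE)
  df <- pmax(na + nb - 2, 0)
  s2 <- ifelse(df > 0, (ssa + ssb) / pmax(df, 1), NA_real_)
  testable <- na >= 2 & nb >= 2
  sq <- squeeze_variances(s2[testable], df[testable], prior_df = prior_df)
  s2_post <- rep(NA_real_, nrow(x))
  s2_post[testable] <- sq$posterior_var
  df_total <- rep(NA_real_, nrow(x))
  df_total[testable] <- df[testable] + sq$prior_df
  fc <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- rep(NA_real_, nrow(x))
  pval <- rep(NA_real_, nrow(x))
  ok <- testable & !is.na(se)
  deg <- ok & se == 0  # zero posterior variance: degenerate rows
  tstat[deg] <- ifelse(fc[deg] == 0, 0, sign(fc[deg]) * Inf)
  pval[deg] <- ifelse(fc[deg] == 0, 1, 0)
  reg <- ok & se > 0
  tstat[reg] <- fc[reg] / se[reg]
  pval[reg] <- 2 * stats::pt(-abs(tstat[reg]), df = df_total[reg])
  adj <- rep(NA_real_, nrow(x))
  adj[!is.na(pval)] <- bh_adjust(pval[!is.na(pval)])
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  tab <- data.frame(feature_id = ids, log2_fc = fc, mean_a = ma, mean_b = mb,
                    t = tstat, p_value = pval, adj_p = adj,
                    n_valid_a = na, n_valid_b = nb, df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 prior_df = sq$prior_df, prior_var = sq$prior_var,
                 posterior_var = s2_post, df_residual = df,
                 group_a = group_a, group_b = group_b,
                 n_a = length(ia), n_b = length(ib)),
            class = "modt")
}

#' Shrink per-feature variances toward a common prior
#'
#' Moment estimator for the parameters of the scaled-F model of sample
#' variances: assuming \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)}, the prior degrees
#' of freedom \eqn{d_0} and prior variance \eqn{s_0^2} are estimated from the
#' mean and excess variance of \eqn{\log s_g^2} (via digamma/trigamma
#' moments), and each feature's posterior variance is the df-weighted convex
#' combination of its own variance and the prior.
#'
#' @param s2 per-feature sample variances (non-negative).
#' @param df residual degrees of freedom, scalar or per-feature.
#' @param prior_df optional fixed prior df overriding the estimate.
#' @return list with `prior_df`, `prior_var`, `posterior_var`.
#' @export
squeeze_variances <- function(s2, df, prior_df = NULL) {
  n <- length(s2)
  if (length(df) == 1L) df <- rep(df, n)
  if (n == 0L)
    return(list(prior_df = prior_df %||% 0, prior_var = NA_real_,
                posterior_var = numeric(0)))
  usable <- is.finite(s2) & df > 0
  if (!any(usable) || all(s2[usable] == 0)) {
    # all-constant input: no variance information to pool
    d0 <- prior_df %||% 0
    return(list(prior_df = d0, prior_var = 0, posterior_var = s2))
  }
  # moment fit is run even when prior_df is overridden (prior_var is needed)
  {
    z <- log(pmax(s2[usable], 1e-300))
    d1 <- df[usable]
    e <- z - digamma(d1 / 2) + log(d1 / 2)
    emean <- mean(e)
    evar <- if (sum(usable) > 1) sum((e - emean)^2) / (sum(usable) - 1) else 0
    evar <- evar - mean(trigamma(d1 / 2))
    if (evar > 0) {
      d0_hat <- 2 * trigamma_inverse(evar)
      s0 <- exp(emean + digamma(d0_hat / 2) - log(d0_hat / 2))
    } else {
      d0_hat <- Inf
      s0 <- exp(emean)
    }
  }
  d0 <- prior_df %||% d0_hat
  post <- if (is.infinite(d0)) rep(s0, n) else
    (df * s2 + d0 * s0) / pmax(df + d0, .Machine$double.eps)
  post[df == 0] <- if (is.infinite(d0)) s0 else if (d0 > 0) s0 else NA_real_
  list(prior_df = d0, prior_var = s0, posterior_var = post)
}

# Newton solve of trigamma(y) = x (monotone decreasing), vectorized.
trigamma_inverse <- function(x) {
  out <- x
  small <- x < 1e-6
  big <- x > 1e7
  out[small] <- 1 / x[small]
  out[big] <- 1 / sqrt(x[big])
  mid <- !(small | big)
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' @export
print.modt <- function(x, ...) {
  cat(sprintf("Moderated t-test: %s vs %s (%d vs %d samples, %d features)\n",
              x$group_a, x$group_b, x$n_a, x$n_b, nrow(x$table)))
  cat(sprintf("  prior df: %s, prior variance: %.4g\n",
              format(x$prior_df, digits = 4), x$prior_var))
  invisible(x)
}

#' @export
summary.modt <- function(object, fdr = 0.05, ...) {
  tab <- object$table
  ns <- sum(!is.na(tab$adj_p))
  sig <- sum(tab$adj_p <= fdr, na.rm = TRUE)
  up <- sum(tab$adj_p <= fdr & tab$log2_fc > 0, na.rm = TRUE)
  cat(sprintf("Moderated t-test %s vs %s\n", object$group_a, object$group_b))
  cat(sprintf("  features tested: %d of %d\n", ns, nrow(tab)))
  cat(sprintf("  significant at FDR %.2g: %d (%d up, %d down)\n",
              fdr, sig, up, sig - up))
  cat(sprintf("  prior df %s, prior variance %.4g\n",
              format(object$prior_df, digits = 4), object$prior_var))
  invisible(list(n_tested = ns, n_significant = sig, n_up = up,
                 n_down = sig - up, prior_df = object$prior_df,
                 prior_var = object$prior_var))
}

#' @export
coef.modt <- function(object, ...) {
  stats::setNames(object$table$log2_fc, object$table$feature_id)
}

#' @export
as.data.frame.modt <- function(x, ...) x$table

#' Volcano plot of a moderated t-test fit
#'
#' @param x a `modt` fit.
#' @param thresholds optional [threshold_config()]; significant features are
#'   highlighted and the cutoffs drawn as dashed lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.modt <- function(x, thresholds = NULL, ...) {
  tab <- x$table
  lp <- -log10(pmax(tab$adj_p, 1e-300))
  col <- rep("grey50", nrow(tab))
  if (!is.null(thresholds)) {
    cut <- log2_fc_cutoff(thresholds)
    sig <- !is.na(tab$adj_p) & tab$adj_p <= thresholds$fdr_cutoff &
      abs(tab$log2_fc) >= cut
    col[sig] <- "red"
  }
  graphics::plot(tab$log2_fc, lp, pch = 16, cex = 0.5, col = col,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ "adjusted p"), ...)
  if (!is.null(thresholds)) {
    cut <- log2_fc_cutoff(thresholds)
    graphics::abline(v = c(-cut, cut), lty = 2)
    graphics::abline(h = -log10(thresholds$fdr_cutoff), lty = 2)
  }
  invisible(x)
}

#' Write a differential-test result table as TSV
#'
#' Columns: `feature_id`, `log2_fc`, `t`, `p`, `adj_p`, `n_valid_a`,
#' `n_valid_b`.
#'
#' @param fit a `modt` object (or its `as.data.frame()` result).
#' @param path output path.
#' @export
write_diff_results <- function(fit, path) {
  tab <- if (inherits(fit, "modt")) fit$table else as.data.frame(fit)
  out <- data.frame(feature_id = tab$feature_id, log2_fc = tab$log2_fc,
                    t = tab$t, p = tab$p_value, adj_p = tab$adj_p,
                    n_valid_a = tab$n_valid_a, n_valid_b = tab$n_valid_b)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
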