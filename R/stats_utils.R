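#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validated front-end to the step-up procedure (delegating to
#' [stats::p.adjust()] with `method = "BH"`): adjusted values are capped at
#' 1, monotone in p-value rank, and returned in the original input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values))
    stop("`p_values` must be numeric", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Seeded k-means clustering
#'
#' Deterministic wrapper around [stats::kmeans()]: squared-Euclidean
#' criterion, 10 random restarts, 300-iteration cap, initialized from the
#' given seed so repeated runs give identical labels.
#'
#' @param x numeric matrix (features in rows) or vector; no missing values.
#' @param k number of clusters, at most the number of features.
#' @param seed integer seed.
#' @param nstart,iter_max restart count and iteration cap.
#' @return integer cluster labels in `1..k`, one per feature (row).
#' @export
kmeans_cluster <- function(x, k, seed = 1L, nstart = 10L, iter_max = 300L) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  k <- stop_if_not_count(k, "k", min = 1L)
  if (k > nrow(x))
    stop("`k` (", k, ") exceeds the number of features (", nrow(x), ")",
         call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k >= n_distinct) {
    # k centres for <= k distinct points: every distinct point is its own
    # cluster (the exact optimum); kmeans() itself errors in this regime
    labels <- match(apply(x, 1L, paste, collapse = "\r"),
                    unique(apply(x, 1L, paste, collapse = "\r")))
    return(as.integer(labels))
  }
  fit <- with_seed(seed,
                   stats::kmeans(x, centers = k, nstart = nstart,
                                 iter.max = iter_max))
  as.integer(fit$cluster)
}

#' Row-wise z-scoring
#'
#' Centers every row to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Constant rows map to all-zero rows rather than NaN:
#' after imputation zero-variance features are legitimate.
#'
#' @param x numeric matrix without missing values.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / pmax(ncol(x) - 1L, 1L))
  out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @return \eqn{r^2} in \[0, 1\].
#' @export
squared_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y)^2
}
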