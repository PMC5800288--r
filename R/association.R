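# Statistical layer linking molecular measurements to gonadal-dysgenesis
# phenotypes: Pearson correlation, multiple regression with partial
# coefficients, complete-linkage (furthest-neighbor) hierarchical
# clustering with a deterministic tie-break, two-sample t-test, and the
# GD < 10% phenotype criterion.

#' Pearson product-moment correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List: \code{r}, two-sided \code{p}, \code{n}.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("non-finite values in correlation input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Multiple linear regression with standardized and partial coefficients
#'
#' Ordinary least squares of \code{y} on the columns of \code{X}. Because
#' "standardized coefficient" is used in two senses in this literature,
#' both are reported: \code{coef_zx} is the coefficient of the response on
#' z-scored predictors (it recovers generative betas expressed per
#' predictor standard deviation), and \code{std_coef} is the fully
#' standardized coefficient (z-scored response too; with a single predictor
#' it equals the Pearson correlation). The partial correlation per
#' predictor is derived from its t statistic, r = t / sqrt(t^2 + df).
#' Small-n fits (down to one residual degree of freedom) are supported.
#'
#' @param y Numeric response.
#' @param X Numeric matrix or data frame of predictors (full column rank).
#' @return List of class \code{regression_result}: \code{coefficients}
#'   data.frame (predictor, coef, coef_zx, std_coef, partial_r, t, p),
#'   \code{intercept}, \code{df} residual degrees of freedom, \code{n},
#'   \code{r_squared}.
#' @export
multiple_regression <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p + 1L)
  if (qr(cbind(1, X))$rank < p + 1L) {
    stop("rank-deficient design: predictors are collinear")
  }
  fit <- stats::lm(y ~ X)
  fit_summary <- summary(fit)
  sm <- fit_summary$coefficients
  coefs <- stats::coef(fit)[-1]
  ts <- sm[-1, "t value"]
  ps <- sm[-1, "Pr(>|t|)"]
  df <- fit$df.residual
  sx <- apply(X, 2, stats::sd)
  sy <- stats::sd(y)
  res <- data.frame(
    predictor = colnames(X),
    coef = unname(coefs),
    coef_zx = unname(coefs * sx),
    std_coef = unname(coefs * sx / sy),
    partial_r = unname(ts / sqrt(ts^2 + df)),
    t = unname(ts),
    p = unname(ps),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = res,
                 intercept = unname(stats::coef(fit)[1]),
                 df = df, n = n, r_squared = fit_summary$r.squared),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("multiple regression: n = %d, residual df = %d, R^2 = %.4f\n",
              x$n, x$df, x$r_squared))
  cat(sprintf("intercept: %.4g\n", x$intercept))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Complete-linkage (furthest-neighbor) hierarchical clustering
#'
#' Agglomerative clustering with complete linkage on Euclidean distances
#' over z-scored features. Ties in the minimum inter-cluster distance are
#' broken deterministically toward the pair of clusters with the smallest
#' member labels, so the result is invariant under permutation of the input
#' rows.
#'
#' @param points Numeric matrix or data frame (rows = observations).
#' @param labels Character labels, one per row (default row names or
#'   sequential).
#' @param scale_features Z-score columns before computing distances
#'   (default TRUE; constant columns are left centered at 0).
#' @return An object of class \code{hclust} (merge, height, order, labels),
#'   usable with \code{stats::cophenetic}, \code{plot} and
#'   \code{\link{dendrogram_newick}}.
#' @export
hcluster <- function(points, labels = NULL, scale_features = TRUE) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2)
  if (is.null(labels)) {
    labels <- rownames(points) %||% as.character(seq_len(n))
  }
  stopifnot(length(labels) == n, !anyDuplicated(labels))

  if (scale_features) {
    points <- apply(points, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) col - mean(col) else (col - mean(col)) / s
    })
    points <- matrix(points, nrow = n)
  }
  d <- as.matrix(stats::dist(points))

  # active clusters: list of member row indices; id < 0 singleton (row),
  # id > 0 merge step, as in stats::hclust
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  min_label <- labels  # smallest member label per active cluster
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        a <- active[ai]; b <- active[bi]
        h <- max(d[members[[a]], members[[b]]])
        lab <- sort(c(min_label[a], min_label[b]))
        if (is.null(best) || h < best$h - 1e-12 ||
            (abs(h - best$h) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(a = a, b = b, h = h, lab = lab)
        }
      }
    }
    ida <- ids[best$a]; idb <- ids[best$b]
    merge[step, ] <- sort(c(ida, idb))
    height[step] <- best$h
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    ids[best$a] <- step
    min_label[best$a] <- min(min_label[best$a], min_label[best$b])
    active <- setdiff(active, best$b)
  }

  hc <- list(merge = merge, height = height,
             order = dendrogram_order(merge, n),
             labels = labels, method = "complete",
             dist.method = "euclidean",
             call = match.call())
  class(hc) <- "hclust"
  hc
}

# Leaf order by left-to-right dendrogram traversal (for plotting only).
dendrogram_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  leaves_of_root <- leaves(n - 1L)
  as.integer(leaves_of_root)
}

#' Newick string for a dendrogram
#'
#' @param hc An \code{hclust} object (e.g. from \code{\link{hcluster}}).
#' @return Newick-formatted character scalar.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Two-sample t-test (classical pooled-variance Student form by default)
#'
#' When both groups have zero variance the test degenerates: equal means
#' yield t = 0, p = 1; unequal means yield infinite t, p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch unequal-variance form instead (default FALSE).
#' @return List: \code{t}, two-sided \code{p}.
#' @export
t_test_groups <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Label a gonadal-dysgenesis score as low or high
#'
#' Low means GD strictly below 10.0 percent. In cross A (M females x tested
#' males) the label describes the paternal line's P inducibility; in cross
#' A* (tested females x reference P males) it describes the maternal line's
#' P susceptibility.
#'
#' @param gd_pct GD percentage(s) in [0, 100].
#' @param cross "A" or "A*".
#' @param criterion Threshold (default 10).
#' @return Character vector "low"/"high" with attribute \code{phenotype}
#'   ("inducibility" for cross A, "susceptibility" for cross A*).
#' @export
label_phenotype <- function(gd_pct, cross = c("A", "A*"), criterion = 10) {
  cross <- match.arg(cross)
  stopifnot(all(gd_pct >= 0 & gd_pct <= 100))
  out <- ifelse(gd_pct < criterion, "low", "high")
  attr(out, "phenotype") <- if (cross == "A") "inducibility" else "susceptibility"
  out
}
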