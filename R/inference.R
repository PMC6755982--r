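# Inference around the PLSR fit: cross-validated component selection,
# permutation test of explained variance, bootstrap z-scoring of gene weights,
# winner's-curse correction, and selection/ranking of significant genes.

#' Choose the number of PLSR components by cross-validation
#'
#' Repeated k-fold cross-validation over regions.  For each fold the model is
#' fit on the training regions and the held-out response predicted with
#' 0..\code{max_components} components (0 = training-mean baseline).  Under
#' the default \code{rule = "1se"} the selected count is the smallest model
#' whose CV error is within one standard error of the minimum (PLS error
#' curves plateau, so the plain minimizer habitually drifts into the plateau);
#' \code{rule = "min"} returns the strict minimizer.  Ties break toward fewer
#' components in both rules.
#'
#' @param x region x gene matrix.
#' @param y response vector (or delta-ct data frame).
#' @param max_components largest model searched (the full analysis default in
#'   this literature is 35).
#' @param folds,repeats CV scheme: \code{folds}-fold, repeated \code{repeats}
#'   times (default 10-fold, 5 repeats); \code{folds = nrow(x)} gives LOO.
#' @param rule \code{"1se"} (default) or \code{"min"}.
#' @param seed RNG seed for fold assignment.
#' @param scale. passed to \code{\link{fit_plsr}}.
#' @return object of class \code{"pls_cv"}: list with \code{ncomp} (selected
#'   count, possibly 0), \code{cv_error} (RMSEP for 0..max components),
#'   \code{cv_se} (fold-to-fold standard errors) and the scheme.
#' @export
select_n_components <- function(x, y, max_components = 35L, folds = 10L,
                                repeats = 5L, rule = c("1se", "min"),
                                seed = 1L, scale. = TRUE) {
  if (is.data.frame(y) && all(c("region_id", "delta_ct") %in% names(y)))
    y <- stats::setNames(y$delta_ct, y$region_id)
  rule <- match.arg(rule)
  x <- as.matrix(x)
  n <- nrow(x)
  .assert_count(max_components, "max_components")
  if (folds > n) stop("fewer regions (", n, ") than folds (", folds, ")")
  if (folds < 2L) stop("folds must be >= 2")
  max_components <- min(max_components, n - ceiling(n / folds) - 1L, ncol(x))
  if (max_components < 1L) stop("too few regions for cross-validation")

  set.seed(seed)
  # per-(repeat, fold) mean squared prediction error, per component count
  fold_mse <- matrix(NA_real_, repeats * folds, max_components + 1L)
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      row <- row + 1L
      test <- fold_id == f
      fit <- fit_plsr(x[!test, , drop = FALSE], y[!test],
                      ncomp = max_components, scale. = scale.)
      fold_mse[row, 1L] <- mean((y[test] - fit$y_mean)^2)
      for (k in seq_len(max_components)) {
        pred <- predict(fit, x[test, , drop = FALSE], ncomp = k)
        fold_mse[row, k + 1L] <- mean((y[test] - pred)^2)
      }
    }
  }
  mse <- colMeans(fold_mse)
  se <- apply(fold_mse, 2L, stats::sd) / sqrt(nrow(fold_mse))
  cv_error <- sqrt(mse)
  names(cv_error) <- names(se) <- 0:max_components
  k_min <- which.min(mse)
  k_sel <- if (rule == "min") k_min else
    which(mse <= mse[k_min] + se[k_min])[1L]
  structure(list(ncomp = k_sel - 1L, ncomp_min = k_min - 1L,
                 cv_error = cv_error, cv_se = se, rule = rule,
                 folds = folds, repeats = repeats, seed = seed),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf(
    "PLSR component selection (%d-fold CV, %d repeat(s)): %d component(s)\n",
    x$folds, x$repeats, x$ncomp))
  cat("  RMSEP (0 = mean-only baseline):\n")
  print(round(x$cv_error, 4))
  invisible(x)
}

#' Permutation test of per-component explained variance
#'
#' The response is randomly permuted across regions \code{B} times and the
#' model refit; the permutation p-value of each component is the add-one
#' estimator \eqn{(1 + \#\{null \ge observed\}) / (B + 1)} on the fraction of
#' response variance explained, so p is never 0.
#'
#' @inheritParams select_n_components
#' @param ncomp number of components in the refitted models.
#' @param B number of permutations (the full analysis default in this
#'   literature is 10,000).
#' @param seed RNG seed.
#' @return object of class \code{"pls_perm"}: a data frame (component,
#'   observed_variance, p_perm) with the B x ncomp null matrix in
#'   \code{attr(, "null_variances")}.
#' @export
permutation_test_components <- function(x, y, ncomp = 1L, B = 10000L,
                                        seed = 1L, scale. = TRUE) {
  if (is.data.frame(y) && all(c("region_id", "delta_ct") %in% names(y)))
    y <- stats::setNames(y$delta_ct, y$region_id)
  x <- as.matrix(x)
  .assert_count(B, "B")
  fit <- fit_plsr(x, y, ncomp = ncomp, scale. = scale.)
  obs <- fit$y_variance_explained

  sx <- .standardize(x, scale. = scale.)
  xs <- sx$x[, !sx$zero_var, drop = FALSE]
  yc <- y - mean(y)
  set.seed(seed)
  null <- matrix(NA_real_, B, ncomp)
  for (b in seq_len(B)) {
    null[b, ] <- .pls_engine(xs, sample(yc), ncomp)$y_variance_explained
  }
  p <- (1 + colSums(null >= rep(obs, each = B))) / (B + 1)
  out <- data.frame(component = seq_len(ncomp), observed_variance = obs,
                    p_perm = p)
  attr(out, "null_variances") <- null
  class(out) <- c("pls_perm", "data.frame")
  out
}

#' Bootstrap z-scores for PLSR gene weights
#'
#' Regions (rows) are resampled with replacement \code{n_boot} times and the
#' model refit on each replicate.  Each replicate's component is sign-aligned
#' to the original fit (flipped when its correlation with the reference weight
#' vector is negative) before accumulating; the bootstrap SE is the SD of the
#' aligned replicate weights, and \eqn{z = w / se}.  Replicates with fewer
#' than 3 distinct regions are redrawn.
#'
#' @inheritParams select_n_components
#' @param component which component's weights to z-score (default 1).
#' @param n_boot number of bootstrap replicates (full-analysis default 1,000).
#' @param ncomp components in each refit (default: \code{component}).
#' @param seed RNG seed.
#' @return a gene-weight table: data frame (gene_id, weight, se_boot, z)
#'   ordered as the expression columns, class \code{"gene_weight_table"}.
#' @seealso \code{\link{fiqt_adjust}}, \code{\link{select_significant}}
#' @export
bootstrap_weights <- function(x, y, component = 1L, n_boot = 1000L,
                              ncomp = component, seed = 1L, scale. = TRUE) {
  if (is.data.frame(y) && all(c("region_id", "delta_ct") %in% names(y)))
    y <- stats::setNames(y$delta_ct, y$region_id)
  x <- as.matrix(x)
  .assert_count(n_boot, "n_boot")
  stopifnot(component >= 1L, component <= ncomp)
  ref <- fit_plsr(x, y, ncomp = ncomp, scale. = scale.)
  x <- x[, ref$gene_ids, drop = FALSE]  # reference gene universe
  w_ref <- ref$weights[, component]
  n <- nrow(x)

  set.seed(seed)
  wb <- matrix(NA_real_, length(w_ref), n_boot)
  for (b in seq_len(n_boot)) {
    for (try in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L) break
      if (try == 100L) stop("could not draw a bootstrap sample with >= 3 distinct regions")
    }
    sx <- .standardize(x[idx, , drop = FALSE], scale. = scale.)
    yb <- y[idx]
    w <- .pls_engine(sx$x, yb - mean(yb), component)$weights[, component]
    s <- sum(w * w_ref)
    if (is.finite(s) && s < 0) w <- -w
    wb[, b] <- w
  }
  se <- apply(wb, 1L, stats::sd)
  if (any(se <= 0))
    stop("bootstrap SE is zero for ", sum(se <= 0), " gene(s)")
  out <- data.frame(gene_id = ref$gene_ids, weight = unname(w_ref),
                    se_boot = se, z = unname(w_ref) / se,
                    stringsAsFactors = FALSE)
  attr(out, "component") <- as.integer(component)
  attr(out, "n_boot") <- as.integer(n_boot)
  class(out) <- c("gene_weight_table", "data.frame")
  out
}

#' FDR inverse quantile transformation of z-scores
#'
#' Counteracts winner's-curse bias in selected effect estimates: two-sided
#' p-values are computed from the z-scores, Benjamini-Hochberg adjusted, and
#' mapped back to same-signed normal quantiles,
#' \eqn{z_{fiqt} = sign(z)\,\Phi^{-1}(1 - p_{adj}/2)}.  Magnitudes shrink
#' (\eqn{|z_{fiqt}| \le |z|}) and the ordering of \eqn{|z|} is preserved;
#' \eqn{p_{adj} = 1} maps to 0.
#'
#' @param z numeric vector of finite z-scores.
#' @return numeric vector of adjusted z-scores, same length and order.
#' @export
fiqt_adjust <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(stats::p.adjust(p, method = "BH"), 1)
  # upper-tail form keeps precision for very small adjusted p
  sign(z) * stats::qnorm(p_adj / 2, lower.tail = FALSE)
}

#' Attach winner's-curse-corrected z and significance flags to a weight table
#'
#' Adds \code{z_fiqt} (\code{\link{fiqt_adjust}} of \code{z}) and
#' \code{significant} (\code{|z_fiqt| > threshold}; selection is by unsigned
#' magnitude because with a signed response the weight sign carries no
#' directional meaning).
#'
#' @param table a gene-weight table from \code{\link{bootstrap_weights}}.
#' @param threshold z threshold, default 1.96 (two-sided q < 0.05).
#' @return the table with columns \code{z_fiqt} and \code{significant} added.
#' @export
adjust_weight_table <- function(table, threshold = 1.96) {
  stopifnot(is.data.frame(table), "z" %in% names(table))
  table$z_fiqt <- fiqt_adjust(table$z)
  table$significant <- abs(table$z_fiqt) > threshold
  table
}

#' Select significant genes from a weight table
#'
#' Genes with \code{|z_fiqt|} above the threshold (unsigned rule).
#'
#' @inheritParams adjust_weight_table
#' @return character vector of gene ids.
#' @export
select_significant <- function(table, threshold = 1.96) {
  stopifnot(is.data.frame(table), "z_fiqt" %in% names(table))
  table$gene_id[abs(table$z_fiqt) > threshold]
}

#' Correlation between component scores and the response map
#'
#' Pearson correlation of a component's regional scores with the response
#' (e.g. \eqn{\Delta CT}) and its two-sided p-value.
#'
#' @param fit a \code{"plsr_fit"}.
#' @param y response vector; defaults to the fitted response.
#' @param component component index.
#' @return list with \code{r} and \code{p}.
#' @export
score_delta_correlation <- function(fit, y = fit$y, component = 1L) {
  stopifnot(inherits(fit, "plsr_fit"), component >= 1L, component <= fit$ncomp)
  if (is.data.frame(y) && all(c("region_id", "delta_ct") %in% names(y)))
    y <- stats::setNames(y$delta_ct, y$region_id)
  s <- fit$scores[, component]
  if (stats::sd(s) == 0) stop("component scores are constant; correlation undefined")
  ct <- stats::cor.test(s, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Top genes by corrected-weight magnitude
#'
#' Ranks genes by \eqn{|z_{fiqt}|} (ties by \eqn{|weight|}, then gene id) and
#' returns the top \code{k} (the ~1\% convention at whole-genome scale is
#' k = 200).
#'
#' @param table a gene-weight table with \code{z_fiqt}.
#' @param k number of genes to return.
#' @return the top-k rows of the table, ranked.
#' @export
top_fraction_genes <- function(table, k = 200L) {
  stopifnot(is.data.frame(table), "z_fiqt" %in% names(table))
  .assert_count(k, "k")
  if (k > nrow(table)) stop("k exceeds the number of genes (", nrow(table), ")")
  ord <- order(-abs(table$z_fiqt), -abs(table$weight), table$gene_id)
  out <- table[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
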