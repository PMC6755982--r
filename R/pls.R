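# Single-response partial least squares regression (NIPALS, sequential
# deflation).  With one response, each component's weight vector is the
# normalized cross-covariance between the deflated predictors and the deflated
# response; in particular component-1 weights are proportional to X'y.
# Sequential deflation means earlier components are unaffected by how many
# components are requested in total.

# low-level engine on a pre-centered/scaled X and centered y
.pls_engine <- function(xs, yc, ncomp) {
  n <- nrow(xs); p <- ncol(xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- sum(yc^2)
  ssx <- sum(xs^2)
  varexp_y <- numeric(ncomp)
  varexp_x <- numeric(ncomp)
  Xk <- xs; yk <- yc
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xk, yk)
    nw <- sqrt(sum(w^2))
    if (nw <= .Machine$double.eps * p)
      stop("degenerate component ", k,
           ": predictor-response covariance is numerically zero")
    w <- w / nw
    tk <- drop(Xk %*% w)
    tt <- sum(tk^2)
    pk <- drop(crossprod(Xk, tk)) / tt
    qk <- sum(yk * tk) / tt
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; q[k] <- qk
    varexp_y[k] <- qk^2 * tt / ssy
    varexp_x[k] <- tt * sum(pk^2) / ssx
    Xk <- Xk - tcrossprod(tk, pk)
    yk <- yk - qk * tk
  }
  list(weights = W, loadings = P, scores = Tm, q = q,
       y_variance_explained = varexp_y, x_variance_explained = varexp_x)
}

#' Fit a partial least squares regression of a regional map on expression
#'
#' Fits single-response PLSR (NIPALS with sequential deflation) of a
#' per-region response -- typically the case-control thickness difference
#' \eqn{\Delta CT} -- on a region x gene expression matrix.  Predictor columns
#' are z-scored across regions by default; zero-variance genes are dropped
#' with a message.  Component-1 gene weights are proportional to the
#' gene-response cross-covariance \eqn{X'y}, and weights of earlier components
#' do not change when more components are requested.
#'
#' @param x region x gene numeric matrix (column names = gene ids).
#' @param y numeric response, one value per row of \code{x} (a named vector
#'   from \code{\link{align_regions}}, or a delta-ct data frame).
#' @param ncomp number of components; at most \code{min(nrow(x) - 1, ncol(x))}.
#' @param scale. z-score predictor columns (default \code{TRUE}).
#' @return an object of class \code{"plsr_fit"}: weights (genes x components),
#'   scores (regions x components), loadings, per-component fractions of
#'   response and predictor variance explained, centering/scaling constants
#'   and the dropped-gene ids.
#' @seealso \code{\link{select_n_components}},
#'   \code{\link{permutation_test_components}}, \code{\link{bootstrap_weights}}
#' @export
fit_plsr <- function(x, y, ncomp = 1L, scale. = TRUE) {
  if (is.data.frame(y) && all(c("region_id", "delta_ct") %in% names(y)))
    y <- stats::setNames(y$delta_ct, y$region_id)
  x <- as.matrix(x)
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    if (!setequal(names(y), rownames(x)))
      stop("rows of x and names of y refer to different regions; align first")
    y <- y[rownames(x)]
  }
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(y) == 0) stop("response is constant (degenerate response)")
  .assert_count(ncomp, "ncomp")
  if (ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("ncomp must be <= min(nrow(x) - 1, ncol(x)) = ",
         min(nrow(x) - 1L, ncol(x)))

  sx <- .standardize(x, scale. = scale.)
  dropped <- colnames(x)[sx$zero_var]
  if (length(dropped)) {
    message("fit_plsr: dropped ", length(dropped), " zero-variance gene(s)")
    keep <- !sx$zero_var
    sx$x <- sx$x[, keep, drop = FALSE]
    sx$center <- sx$center[keep]; sx$scale <- sx$scale[keep]
  }
  y_mean <- mean(y)
  eng <- .pls_engine(sx$x, y - y_mean, ncomp)
  gene_ids <- colnames(sx$x)
  dimnames(eng$weights) <- list(gene_ids, paste0("comp", seq_len(ncomp)))
  dimnames(eng$loadings) <- dimnames(eng$weights)
  dimnames(eng$scores) <- list(rownames(x), paste0("comp", seq_len(ncomp)))
  structure(c(eng, list(ncomp = as.integer(ncomp), y = y, y_mean = y_mean,
                        x_center = sx$center, x_scale = sx$scale,
                        scale. = scale., dropped_genes = dropped,
                        gene_ids = gene_ids, call = match.call())),
            class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR fit: %d region(s) x %d gene(s), %d component(s)\n",
              nrow(x$scores), length(x$gene_ids), x$ncomp))
  cat("  response variance explained per component:\n   ",
      paste(sprintf("%.3f", x$y_variance_explained), collapse = " "), "\n")
  if (length(x$dropped_genes))
    cat("  dropped zero-variance genes:", length(x$dropped_genes), "\n")
  invisible(x)
}

#' @export
summary.plsr_fit <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$ncomp),
                    y_var_explained = object$y_variance_explained,
                    y_var_cumulative = cumsum(object$y_variance_explained),
                    x_var_explained = object$x_variance_explained)
  structure(list(table = tab, n_regions = nrow(object$scores),
                 n_genes = length(object$gene_ids)),
            class = "summary.plsr_fit")
}

#' @export
print.summary.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR over %d regions and %d genes\n", x$n_regions, x$n_genes))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regression coefficients of a PLSR fit
#'
#' Coefficients of the \code{ncomp}-component prediction rule on the original
#' predictor scale, with the intercept as attribute \code{"intercept"}.
#'
#' @param object a \code{"plsr_fit"}.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return named numeric vector of per-gene coefficients.
#' @export
coef.plsr_fit <- function(object, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1L, ncomp <= object$ncomp)
  k <- seq_len(ncomp)
  W <- object$weights[, k, drop = FALSE]
  P <- object$loadings[, k, drop = FALSE]
  b_std <- drop(W %*% solve(crossprod(P, W), object$q[k]))
  b <- b_std / object$x_scale
  attr(b, "intercept") <- object$y_mean - sum(b * object$x_center)
  b
}

#' @export
predict.plsr_fit <- function(object, newdata = NULL, ncomp = object$ncomp, ...) {
  b <- coef(object, ncomp = ncomp)
  if (is.null(newdata)) {
    k <- seq_len(ncomp)
    return(object$y_mean +
             drop(object$scores[, k, drop = FALSE] %*% object$q[k]))
  }
  newdata <- as.matrix(newdata)[, object$gene_ids, drop = FALSE]
  drop(newdata %*% b) + attr(b, "intercept")
}

#' @export
fitted.plsr_fit <- function(object, ...) predict(object)

#' @export
residuals.plsr_fit <- function(object, ...) object$y - fitted(object)

#' Diagnostic plots for a PLSR fit
#'
#' Two base-graphics panels: per-component response variance explained, and
#' component scores against the response.
#'
#' @param x a \code{"plsr_fit"}.
#' @param component component for the score panel (default 1).
#' @param ... passed to \code{barplot}/\code{plot}.
#' @return invisibly, \code{x}.
#' @export
plot.plsr_fit <- function(x, component = 1L, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(x$y_variance_explained,
                    names.arg = seq_len(x$ncomp),
                    xlab = "component", ylab = "response variance explained",
                    ...)
  graphics::plot(x$scores[, component], x$y,
                 xlab = sprintf("component %d scores", component),
                 ylab = "response", ...)
  invisible(x)
}
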