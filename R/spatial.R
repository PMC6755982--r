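# Spatial characterization of a gene set across Von Economo classes.

#' Per-region expression score of a gene set
#'
#' Each gene's expression is z-scored across regions, then the score of a
#' region is the mean standardized expression over the gene set.  Genes with
#' zero variance across regions carry no spatial information and are dropped
#' with a warning.
#'
#' @param expr region x gene matrix.
#' @param genes character vector of gene ids (subset of the matrix columns).
#' @return named numeric vector, one score per region.
#' @export
regional_set_score <- function(expr, genes) {
  stopifnot(is.matrix(expr))
  if (!length(genes)) stop("gene set is empty")
  missing <- setdiff(genes, colnames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sub <- expr[, genes, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropped ", sum(sds == 0),
            " zero-variance gene(s) from the set score")
    sub <- sub[, sds > 0, drop = FALSE]
    if (!ncol(sub)) stop("no genes with positive variance in the set")
  }
  rowMeans(scale(sub))
}

#' Von Economo class enrichment of a gene set with a permutation null
#'
#' For each cytoarchitectonic class, compares the observed class mean of the
#' gene set's regional score against a null distribution built from \code{B}
#' random gene sets of the same size drawn from the measured-gene universe
#' (preserving the cortical spatial covariance).  Reports per class the
#' z-score \eqn{(obs - null\,mean)/null\,sd}, a two-tailed add-one permutation
#' p-value, the BH-adjusted q across classes, and the direction, significant
#' at q < \code{alpha} per tail.
#'
#' @param expr region x gene matrix.
#' @param annot data frame (region_id, ve_class) covering the matrix rows.
#' @param genes gene-id set to characterize.
#' @param B number of random gene sets (default 1,000).
#' @param seed RNG seed.
#' @param alpha per-tail significance level on q (default 0.025, i.e. a
#'   two-tailed 0.05).
#' @return data frame of class \code{"ve_profile"}: ve_class, n_regions,
#'   observed_mean, null_mean, null_sd, z, p_perm, q, direction.  The B x
#'   class null matrix is in \code{attr(, "null_means")}.
#' @export
ve_enrichment <- function(expr, annot, genes, B = 1000L, seed = 1L,
                          alpha = 0.025) {
  stopifnot(is.matrix(expr), is.data.frame(annot),
            all(c("region_id", "ve_class") %in% names(annot)))
  .assert_count(B, "B")
  if (!all(rownames(expr) %in% annot$region_id))
    stop("annotation must cover every region of the expression matrix")
  ve <- annot$ve_class[match(rownames(expr), annot$region_id)]

  # universe = genes with positive variance; standardize once
  sds <- apply(expr, 2L, stats::sd)
  universe <- colnames(expr)[sds > 0]
  classes <- sort(unique(ve))
  if (!length(universe)) {
    # no spatial structure at all: every class mean is 0 by convention
    out <- data.frame(ve_class = classes,
                      n_regions = as.integer(table(ve)[as.character(classes)]),
                      observed_mean = 0, null_mean = 0, null_sd = 0,
                      z = 0, p_perm = 1, q = 1, direction = "none",
                      stringsAsFactors = FALSE)
    class(out) <- c("ve_profile", "data.frame")
    return(out)
  }
  zx <- scale(expr[, universe, drop = FALSE])
  genes_used <- intersect(genes, universe)
  if (!length(genes_used)) stop("gene set has no measured, non-constant genes")
  if (length(genes_used) < length(genes))
    warning("dropped ", length(genes) - length(genes_used),
            " gene(s) not usable for the set score")

  # per-class mean of the set score = mean over class regions and set genes
  class_gene_mean <- t(vapply(classes, function(cl) {
    colMeans(zx[ve == cl, , drop = FALSE])
  }, numeric(ncol(zx))))  # classes x genes
  rownames(class_gene_mean) <- classes
  obs <- rowMeans(class_gene_mean[, genes_used, drop = FALSE])

  set.seed(seed)
  k <- length(genes_used)
  null <- matrix(NA_real_, B, length(classes),
                 dimnames = list(NULL, classes))
  for (b in seq_len(B)) {
    idx <- sample.int(ncol(zx), k)
    null[b, ] <- rowMeans(class_gene_mean[, idx, drop = FALSE])
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2L, stats::sd)
  z <- (obs - null_mean) / null_sd
  p_hi <- (1 + colSums(null >= rep(obs, each = B))) / (B + 1)
  p_lo <- (1 + colSums(null <= rep(obs, each = B))) / (B + 1)
  p <- pmin(2 * pmin(p_hi, p_lo), 1)
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(q < alpha, ifelse(z > 0, "over", "under"), "none")

  out <- data.frame(ve_class = classes,
                    n_regions = as.integer(table(ve)[as.character(classes)]),
                    observed_mean = obs, null_mean = null_mean,
                    null_sd = null_sd, z = z, p_perm = p, q = q,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_means") <- null
  attr(out, "n_genes_used") <- k
  class(out) <- c("ve_profile", "data.frame")
  out
}

#' Barplot of Von Economo class z-scores
#'
#' @param x a \code{"ve_profile"}.
#' @param ... passed to \code{barplot}.
#' @return invisibly, \code{x}.
#' @export
plot.ve_profile <- function(x, ...) {
  cols <- ifelse(x$direction == "over", "firebrick",
                 ifelse(x$direction == "under", "steelblue", "grey70"))
  graphics::barplot(x$z, names.arg = x$ve_class, col = cols,
                    xlab = "Von Economo class", ylab = "z-score", ...)
  invisible(x)
}
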