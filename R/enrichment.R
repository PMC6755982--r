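# Gene-set enrichment of the significant PLSR genes: gene-length-adjusted
# logistic regression, cell-type marker sets, and local over-representation.

#' Logistic-regression enrichment of one candidate gene set
#'
#' Over the measured-gene universe, fits
#' \code{candidate_membership ~ target_membership + log(gene length)} by
#' logistic regression; the enrichment odds ratio is the exponentiated target
#' coefficient with its Wald 95\% CI and two-sided p.  With a constant (or
#' absent) covariate this reduces to the marginal 2x2 odds ratio.  When a 2x2
#' cell is empty (separation), the Haldane-Anscombe correction (0.5 added to
#' each cell) is used instead and the result flagged.
#'
#' @param target gene-id set (e.g. the significant PLSR genes).
#' @param candidate gene-id set being tested for enrichment.
#' @param universe character vector: the measured-gene universe.
#' @param covariates optional data frame (gene_id, length_bp) supplying the
#'   gene-length covariate; \code{NULL} fits the unadjusted model.
#' @return one-row data frame: or_estimate, ci_low, ci_high, p, n_overlap,
#'   corrected (logical: Haldane-Anscombe fallback used).
#' @export
logistic_enrichment <- function(target, candidate, universe,
                                covariates = NULL) {
  universe <- unique(as.character(universe))
  target <- intersect(target, universe)
  candidate <- intersect(candidate, universe)
  in_t <- universe %in% target
  in_c <- universe %in% candidate
  n_overlap <- sum(in_t & in_c)

  cells <- c(a = sum(in_t & in_c), b = sum(!in_t & in_c),
             c = sum(in_t & !in_c), d = sum(!in_t & !in_c))
  if (any(cells == 0)) {
    # separation: corrected 2x2 (covariate adjustment is meaningless here)
    a <- cells + 0.5
    log_or <- log(a[["a"]] * a[["d"]] / (a[["b"]] * a[["c"]]))
    se <- sqrt(sum(1 / a))
  } else {
    df <- data.frame(y = as.integer(in_c), x = as.integer(in_t))
    form <- y ~ x
    if (!is.null(covariates)) {
      len <- covariates$length_bp[match(universe, covariates$gene_id)]
      if (any(is.na(len) | len <= 0))
        stop("covariates must provide a positive length_bp for every universe gene")
      df$log_length <- log(len)
      if (stats::sd(df$log_length) > 0) form <- y ~ x + log_length
    }
    fit <- stats::glm(form, family = stats::binomial(), data = df)
    log_or <- stats::coef(fit)[["x"]]
    se <- sqrt(stats::vcov(fit)["x", "x"])
  }
  zval <- log_or / se
  data.frame(or_estimate = exp(log_or),
             ci_low = exp(log_or - 1.96 * se),
             ci_high = exp(log_or + 1.96 * se),
             p = 2 * stats::pnorm(-abs(zval)),
             n_overlap = n_overlap,
             corrected = any(cells == 0))
}

#' Enrichment of a gene-set collection, corrected within families
#'
#' Runs \code{\link{logistic_enrichment}} of the target set against every set
#' in the collection, then adjusts p-values within each family:
#' Benjamini-Hochberg everywhere except the \code{cell_type} family, which
#' uses Bonferroni (its marker sets are nearly disjoint).  A set is flagged
#' enriched when q < \code{alpha} and OR > 1.
#'
#' @param target gene-id set.
#' @param collection a \code{\link{gene_set_collection}}.
#' @param universe measured-gene universe.
#' @param covariates optional gene-length covariate table (gene_id, length_bp).
#' @param alpha significance level on q (default 0.05).
#' @return data frame of class \code{"enrichment_result"}: family, set_name,
#'   or_estimate, ci_high, ci_low, p, q, n_overlap, corrected, enriched.
#' @export
enrich_families <- function(target, collection, universe, covariates = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("empty gene-set collection")
  rows <- lapply(names(collection$sets), function(nm) {
    r <- logistic_enrichment(target, collection$sets[[nm]], universe,
                             covariates)
    cbind(data.frame(family = collection$family[[nm]], set_name = nm,
                     stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (f in unique(out$family)) {
    i <- out$family == f
    method <- if (f == "cell_type") "bonferroni" else "BH"
    out$q[i] <- stats::p.adjust(out$p[i], method = method)
  }
  out$enriched <- out$q < alpha & out$or_estimate > 1
  out <- out[c("family", "set_name", "or_estimate", "ci_high", "ci_low",
               "p", "q", "n_overlap", "corrected", "enriched")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Build cell-type marker gene sets from expression profiles
#'
#' For each cell class, genes are ranked by the log fold-difference of that
#' class's expression against the mean of the remaining classes
#' (\code{log((x + 1) / (mean(others) + 1))}, pseudocount 1) and the top
#' \code{top_n} genes form the marker set.  Ties break by gene id, so the
#' sets are deterministic and invariant to input row order.
#'
#' @param profiles data frame: gene_id plus one nonnegative numeric column per
#'   cell class (at least two classes).
#' @param top_n marker-set size per class (default 500).
#' @return a \code{\link{gene_set_collection}} with family \code{cell_type}.
#' @export
build_celltype_sets <- function(profiles, top_n = 500L) {
  stopifnot(is.data.frame(profiles), "gene_id" %in% names(profiles))
  classes <- setdiff(names(profiles), "gene_id")
  if (length(classes) < 2L) stop("need at least 2 cell classes")
  .assert_count(top_n, "top_n")
  if (top_n > nrow(profiles))
    stop("top_n exceeds the number of genes (", nrow(profiles), ")")
  x <- as.matrix(profiles[classes])
  if (any(x < 0)) stop("cell-type expression must be nonnegative")
  sets <- lapply(classes, function(cl) {
    others <- rowMeans(x[, setdiff(classes, cl), drop = FALSE])
    lfd <- log((x[, cl] + 1) / (others + 1))
    ord <- order(-lfd, profiles$gene_id)
    sort(profiles$gene_id[ord[seq_len(top_n)]])
  })
  names(sets) <- classes
  gene_set_collection(
    sets,
    family = stats::setNames(rep("cell_type", length(classes)), classes),
    description = stats::setNames(
      rep(sprintf("top %d genes by log fold-difference vs other classes",
                  top_n), length(classes)),
      classes))
}

#' Hypergeometric over-representation of pathway sets
#'
#' A local over-representation test: for each pathway set, the one-sided
#' hypergeometric upper-tail p-value of the observed overlap with the target
#' set, given the universe, BH-adjusted across the collection.
#'
#' @param target nonempty gene-id set.
#' @param pathway_sets a \code{\link{gene_set_collection}}.
#' @param universe measured-gene universe.
#' @param alpha significance level on q (default 0.05).
#' @return data frame of class \code{"enrichment_result"}: set_name,
#'   n_overlap, n_set, n_target, p, q, enriched.
#' @export
over_representation <- function(target, pathway_sets, universe, alpha = 0.05) {
  stopifnot(inherits(pathway_sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  target <- intersect(target, universe)
  if (!length(target)) stop("target set is empty within the universe")
  N <- length(universe)
  rows <- lapply(names(pathway_sets$sets), function(nm) {
    s <- intersect(pathway_sets$sets[[nm]], universe)
    k <- length(intersect(s, target))
    # P(overlap >= k) drawing |target| genes from N with |s| marked
    p <- stats::phyper(k - 1, length(s), N - length(s), length(target),
                       lower.tail = FALSE)
    data.frame(set_name = nm, n_overlap = k, n_set = length(s),
               n_target = length(target), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Candidate gene set from gene-level association z-scores
#'
#' Thresholds precomputed gene-level association z-scores (e.g. from
#' SNP-to-gene collapsing of a GWAS) into a candidate set for the logistic
#' enrichment framework.
#'
#' @param gene_meta data frame (gene_id, assoc_z).
#' @param z_threshold inclusion threshold on \code{assoc_z} (default 1.96).
#' @return character vector of gene ids with \code{assoc_z >= z_threshold}.
#' @export
assoc_gene_set <- function(gene_meta, z_threshold = 1.96) {
  stopifnot(all(c("gene_id", "assoc_z") %in% names(gene_meta)))
  gene_meta$gene_id[!is.na(gene_meta$assoc_z) &
                      gene_meta$assoc_z >= z_threshold]
}
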