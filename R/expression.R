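# Region x gene expression assembly, alignment, and gene-set containers.

#' Construct a gene-set collection
#'
#' A named list of gene-id character vectors with a family label and free-text
#' description per set.  Families group sets for multiple-testing correction
#' in enrichment analyses (e.g. \code{dysregulated}, \code{adult_module},
#' \code{fetal_module}, \code{rare_variant}, \code{cell_type},
#' \code{pathway}).
#'
#' @param sets named list of character vectors of gene ids.
#' @param family named character vector (one entry per set); defaults to
#'   \code{"unspecified"}.
#' @param description named character vector; defaults to \code{""}.
#' @return an object of class \code{"gene_set_collection"}.
#' @export
gene_set_collection <- function(sets, family = NULL, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  nm <- names(sets)
  if (is.null(family)) family <- stats::setNames(rep("unspecified", length(nm)), nm)
  if (is.null(description)) description <- stats::setNames(rep("", length(nm)), nm)
  if (!all(nm %in% names(family)) || !all(nm %in% names(description)))
    stop("family and description must cover every set name")
  structure(list(sets = sets, family = family[nm], description = description[nm]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection: %d sets\n", length(x$sets)))
  fam <- table(x$family)
  for (f in names(fam)) cat(sprintf("  %s: %d set(s)\n", f, fam[[f]]))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Duplicate genes within a line are removed with a warning; a line with
#' fewer than three fields is an error reporting the line number.
#'
#' @param path GMT file path.
#' @param family optional family label applied to all sets, or a named vector.
#' @return a \code{\link{gene_set_collection}}.
#' @export
read_gmt <- function(path, family = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L))
    stop("malformed GMT line(s) (fewer than 3 tab-separated fields): ",
         paste(which(nfield < 3L), collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("duplicate gene ids within set(s), deduplicated: ",
            paste(nm[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  if (!is.null(family) && length(family) == 1L && is.null(names(family)))
    family <- stats::setNames(rep(family, length(nm)), nm)
  gene_set_collection(sets, family = family, description = desc)
}

#' Write a gene-set collection to GMT
#'
#' Round-trips with \code{\link{read_gmt}}: set names, descriptions and
#' membership are preserved (family labels are not part of the GMT format and
#' must be re-supplied on read).
#'
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Aggregate sample-level expression to a region x gene matrix
#'
#' Each region's expression is the median over all tissue samples assigned to
#' it, pooled across donors.  Regions with no assigned sample are dropped and
#' reported via a message.  Samples with missing/unassigned region are
#' ignored.
#'
#' @param samples data frame with columns \code{sample_id}, \code{region_id}
#'   (NA = unassigned), optionally \code{donor_id}, plus one numeric column
#'   per gene.
#' @return numeric matrix (regions x genes) with region ids as rownames.
#' @export
aggregate_to_regions <- function(samples) {
  stopifnot(is.data.frame(samples), "region_id" %in% names(samples))
  meta_cols <- intersect(c("sample_id", "donor_id", "region_id"), names(samples))
  gene_cols <- setdiff(names(samples), meta_cols)
  if (!length(gene_cols)) stop("no gene columns in sample table")
  keep <- !is.na(samples$region_id) & nzchar(as.character(samples$region_id))
  if (!any(keep)) stop("all samples are unassigned; empty expression matrix")
  samples <- samples[keep, , drop = FALSE]
  regions <- sort(unique(as.character(samples$region_id)))
  x <- as.matrix(samples[gene_cols])
  idx <- split(seq_len(nrow(samples)), as.character(samples$region_id))
  out <- t(vapply(regions, function(r) {
    apply(x[idx[[r]], , drop = FALSE], 2L, stats::median)
  }, numeric(length(gene_cols))))
  dimnames(out) <- list(regions, gene_cols)
  out
}

#' Align expression, thickness differences and region annotation
#'
#' Restricts all three inputs to their common region set, in a single sorted
#' region order, so rows correspond across objects.  The number of regions
#' dropped from each input is reported via a message and returned.
#'
#' @param expr region x gene matrix with region ids as rownames.
#' @param dct data frame (region_id, delta_ct), as from
#'   \code{\link{compute_delta_ct}}.
#' @param annot data frame (region_id, ve_class); optional.
#' @return list with elements \code{expression}, \code{delta_ct} (named
#'   numeric vector), \code{annotation}, and \code{n_dropped} (named integer
#'   vector per input).
#' @export
align_regions <- function(expr, dct, annot = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  common <- intersect(rownames(expr), dct$region_id)
  if (!is.null(annot)) common <- intersect(common, annot$region_id)
  if (!length(common)) stop("no regions shared across inputs")
  common <- sort(common)
  n_dropped <- c(expression = nrow(expr) - length(common),
                 delta_ct = nrow(dct) - length(common),
                 annotation = if (is.null(annot)) 0L else
                   nrow(annot) - length(common))
  if (any(n_dropped > 0))
    message("align_regions: dropped regions - ",
            paste(names(n_dropped), n_dropped, sep = "=", collapse = ", "))
  y <- stats::setNames(dct$delta_ct, dct$region_id)[common]
  out_annot <- if (is.null(annot)) NULL else {
    a <- annot[match(common, annot$region_id), , drop = FALSE]
    rownames(a) <- NULL
    a
  }
  list(expression = expr[common, , drop = FALSE], delta_ct = y,
       annotation = out_annot, n_dropped = n_dropped)
}

#' Write / read a region x gene expression matrix as TSV
#'
#' First column \code{region_id}, then one column per gene.
#'
#' @param expr region x gene matrix.
#' @param path file path.
#' @return \code{write_expression_tsv}: invisibly, \code{path};
#'   \code{read_expression_tsv}: the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr), expr,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[setdiff(names(df), "region_id")])
  rownames(m) <- df$region_id
  m
}
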