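# Synthetic imaging-transcriptomics bundles with planted ground truth.
#
# The generative model is the minimal linear latent structure under which PLSR
# is the right estimator: a per-region latent spatial factor t_r drives both
# the expression of a designated set of "signal" genes and the true
# case-control cortical-thickness difference.

#' Simulation parameters for a synthetic imaging-transcriptomics bundle
#'
#' Collects and validates all knobs of the generative model.  Defaults emulate
#' a desk-scale version of a multi-site case-control cortical-thickness study
#' paired with a region-by-gene expression matrix: 60 cortical regions, 2,000
#' genes of which 100 carry signal, cohort sizes 62 cases / 87 controls spread
#' over 4 scanner sites.
#'
#' @param n_regions number of cortical regions.
#' @param n_genes number of genes in the expression matrix.
#' @param n_cases,n_controls cohort sizes.
#' @param n_sites number of scanner sites; subjects are assigned at random.
#' @param site_effect_sd SD (mm) of per-site additive thickness offsets.
#' @param latent_effect coupling (mm per latent-factor SD) between the latent
#'   spatial factor and the true regional thickness difference.
#' @param signal_gene_count number of genes loading on the latent factor
#'   (default: 100, capped at \code{n_genes}).
#' @param signal_loading loading of signal genes on the latent factor
#'   (expression units per latent-factor SD).
#' @param noise_sd_expression SD of i.i.d. expression noise.
#' @param noise_sd_ct SD (mm) of per-subject, per-region thickness noise.
#' @param planted_set_size size of the planted "downregulated" gene set
#'   (default: 100, capped at \code{n_genes}).
#' @param planted_set_overlap fraction of the planted set drawn from signal
#'   genes (the rest are random non-signal genes).
#' @param ve_class_count number of Von Economo classes, assigned to contiguous
#'   region blocks.
#' @param n_latent number of latent factors (1 by default; more are useful for
#'   exercising cross-validated component selection).
#' @param spatial_boost additive expression boost of signal genes in regions of
#'   \code{spatial_class}; 0 disables the planted spatial mode.
#' @param spatial_class Von Economo class receiving the spatial boost.
#' @param length_confounded if \code{TRUE}, planted-set genes are drawn with
#'   systematically longer gene lengths, to exercise covariate adjustment.
#' @param seed master seed for the generator.
#'
#' @return an object of class \code{"simulation_params"} (a validated list).
#' @export
simulation_params <- function(n_regions = 60, n_genes = 2000,
                              n_cases = 62, n_controls = 87,
                              n_sites = 4, site_effect_sd = 0.1,
                              latent_effect = 1,
                              signal_gene_count = min(100, n_genes),
                              signal_loading = 1,
                              noise_sd_expression = 0.5, noise_sd_ct = 0.5,
                              planted_set_size = min(100, n_genes),
                              planted_set_overlap = 0.5,
                              ve_class_count = 7, n_latent = 1,
                              spatial_boost = 0, spatial_class = 2L,
                              length_confounded = FALSE, seed = 1L) {
  .assert_count(n_regions, "n_regions")
  .assert_count(n_genes, "n_genes")
  .assert_count(n_cases, "n_cases")
  .assert_count(n_controls, "n_controls")
  .assert_count(n_sites, "n_sites")
  .assert_count(ve_class_count, "ve_class_count")
  .assert_count(n_latent, "n_latent")
  .assert_count(signal_gene_count, "signal_gene_count", min = 0L)
  .assert_count(planted_set_size, "planted_set_size")
  .assert_nonneg(site_effect_sd, "site_effect_sd")
  .assert_nonneg(noise_sd_expression, "noise_sd_expression")
  .assert_nonneg(noise_sd_ct, "noise_sd_ct")
  .assert_fraction(planted_set_overlap, "planted_set_overlap")
  if (signal_gene_count > n_genes)
    stop("signal_gene_count must not exceed n_genes")
  if (planted_set_size > n_genes)
    stop("planted_set_size must not exceed n_genes")
  if (n_sites > n_cases + n_controls)
    stop("n_sites must not exceed the total number of subjects")
  p <- list(n_regions = as.integer(n_regions), n_genes = as.integer(n_genes),
            n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
            n_sites = as.integer(n_sites), site_effect_sd = site_effect_sd,
            latent_effect = latent_effect,
            signal_gene_count = as.integer(signal_gene_count),
            signal_loading = signal_loading,
            noise_sd_expression = noise_sd_expression,
            noise_sd_ct = noise_sd_ct,
            planted_set_size = as.integer(planted_set_size),
            planted_set_overlap = planted_set_overlap,
            ve_class_count = as.integer(ve_class_count),
            n_latent = as.integer(n_latent),
            spatial_boost = spatial_boost,
            spatial_class = as.integer(spatial_class),
            length_confounded = isTRUE(length_confounded),
            seed = as.integer(seed))
  class(p) <- "simulation_params"
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat(sprintf("  %d regions x %d genes (%d signal genes, loading %.3g)\n",
              x$n_regions, x$n_genes, x$signal_gene_count, x$signal_loading))
  cat(sprintf("  cohort: %d cases / %d controls over %d sites (site SD %.3g mm)\n",
              x$n_cases, x$n_controls, x$n_sites, x$site_effect_sd))
  cat(sprintf("  latent effect %.3g mm/SD; noise: expression %.3g, CT %.3g mm; seed %d\n",
              x$latent_effect, x$noise_sd_expression, x$noise_sd_ct, x$seed))
  invisible(x)
}

#' Simulate a self-contained imaging-transcriptomics bundle
#'
#' Generates, under one seed, every input the analysis pipeline consumes plus
#' the generating ground truth: a per-subject regional thickness cohort with
#' scanner-site offsets, a region-by-gene expression matrix with a shared
#' latent spatial factor, Von Economo class annotations on contiguous region
#' blocks, per-gene metadata (length, association z), and a gene-set
#' collection containing one planted "downregulated" set that overlaps the
#' signal genes plus random decoy sets.
#'
#' The generative model per region \eqn{r} and gene \eqn{g}:
#' \deqn{X[r,g] = loading \cdot t_r \cdot 1\{g \in signal\} + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma_x^2)}
#' with latent factor \eqn{t_r \sim N(0,1)}, true difference
#' \eqn{\Delta CT_r = a\, t_r}, and per-subject thickness
#' \eqn{CT[s,r] = baseline_r + group_s\,\Delta CT_r + site_s + N(0,\sigma_{ct}^2)}
#' (cases coded 1, controls 0).
#'
#' @param params a \code{\link{simulation_params}} object.
#' @return an object of class \code{"synthetic_bundle"}: a list with elements
#'   \code{cohort} (long-format data frame: subject_id, group, site, region_id,
#'   thickness), \code{expression} (region x gene matrix), \code{annotation}
#'   (region_id, ve_class), \code{gene_meta} (gene_id, length_bp, assoc_z),
#'   \code{gene_sets} (a \code{gene_set_collection}), \code{truth} (latent
#'   factor, signal gene ids, planted set name, true per-region difference)
#'   and \code{params}.
#' @seealso \code{\link{null_bundle}}, \code{\link{write_bundle}}
#' @export
simulate_bundle <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)

  region_ids <- sprintf("R%03d", seq_len(p$n_regions))
  gene_ids <- sprintf("G%05d", seq_len(p$n_genes))

  # latent spatial factors and signal genes
  latent <- matrix(stats::rnorm(p$n_regions * p$n_latent),
                   p$n_regions, p$n_latent)
  rownames(latent) <- region_ids
  signal_genes <- if (p$signal_gene_count > 0)
    sort(sample(gene_ids, p$signal_gene_count)) else character(0)

  expr <- matrix(stats::rnorm(p$n_regions * p$n_genes,
                              sd = p$noise_sd_expression),
                 p$n_regions, p$n_genes,
                 dimnames = list(region_ids, gene_ids))
  if (p$signal_gene_count > 0 && p$signal_loading != 0) {
    # signal genes split evenly across latent factors
    fac <- rep(seq_len(p$n_latent), length.out = p$signal_gene_count)
    for (l in seq_len(p$n_latent)) {
      g <- signal_genes[fac == l]
      expr[, g] <- expr[, g] + p$signal_loading * latent[, l]
    }
  }

  # Von Economo classes on contiguous region blocks
  ve_class <- as.integer(cut(seq_len(p$n_regions), breaks = p$ve_class_count,
                             labels = FALSE))
  annotation <- data.frame(region_id = region_ids, ve_class = ve_class,
                           stringsAsFactors = FALSE)

  if (p$spatial_boost != 0 && length(signal_genes) > 0) {
    boosted <- region_ids[ve_class == p$spatial_class]
    expr[boosted, signal_genes] <- expr[boosted, signal_genes] + p$spatial_boost
  }

  # true thickness difference and cohort
  true_dct <- p$latent_effect * rowSums(latent) / sqrt(p$n_latent)
  names(true_dct) <- region_ids
  baseline <- 2.5 + 0.1 * stats::rnorm(p$n_regions)
  n_sub <- p$n_cases + p$n_controls
  group <- rep(c("case", "control"), c(p$n_cases, p$n_controls))
  site <- sample(rep_len(sprintf("S%02d", seq_len(p$n_sites)), n_sub))
  site_off <- stats::rnorm(p$n_sites, sd = p$site_effect_sd)
  names(site_off) <- sprintf("S%02d", seq_len(p$n_sites))
  subject_id <- sprintf("sub%04d", seq_len(n_sub))

  thick <- outer(rep(1, n_sub), baseline) +
    outer(as.numeric(group == "case"), true_dct) +
    matrix(site_off[site], n_sub, p$n_regions) +
    matrix(stats::rnorm(n_sub * p$n_regions, sd = p$noise_sd_ct),
           n_sub, p$n_regions)
  cohort <- data.frame(
    subject_id = rep(subject_id, each = p$n_regions),
    group = rep(group, each = p$n_regions),
    site = rep(site, each = p$n_regions),
    region_id = rep(region_ids, times = n_sub),
    thickness = as.vector(t(thick)),
    stringsAsFactors = FALSE)

  # gene metadata: lognormal lengths, standard-normal association z
  length_bp <- round(stats::rlnorm(p$n_genes, meanlog = 9, sdlog = 1))
  assoc_z <- stats::rnorm(p$n_genes)
  gene_meta <- data.frame(gene_id = gene_ids, length_bp = pmax(length_bp, 1),
                          assoc_z = assoc_z, stringsAsFactors = FALSE)

  # planted "downregulated" set + decoys
  n_from_signal <- min(round(p$planted_set_overlap * p$planted_set_size),
                       length(signal_genes))
  non_signal <- setdiff(gene_ids, signal_genes)
  n_rest <- p$planted_set_size - n_from_signal
  if (n_rest > length(non_signal)) {
    # not enough non-signal genes; top the set up from the signal pool
    n_from_signal <- n_from_signal + n_rest - length(non_signal)
    n_rest <- length(non_signal)
  }
  planted <- sort(c(if (n_from_signal) sample(signal_genes, n_from_signal),
                    if (n_rest) sample(non_signal, n_rest)))
  if (p$length_confounded) {
    idx <- match(planted, gene_meta$gene_id)
    gene_meta$length_bp[idx] <-
      pmax(round(stats::rlnorm(length(idx), meanlog = 10.5, sdlog = 1)), 1)
  }
  decoy <- function(n) sort(sample(gene_ids, min(n, p$n_genes)))
  sets <- list(planted_down = planted,
               decoy_up = decoy(100),
               decoy_mod_a = decoy(150),
               decoy_mod_b = decoy(120),
               decoy_rare = decoy(65))
  family <- c(planted_down = "dysregulated", decoy_up = "dysregulated",
              decoy_mod_a = "adult_module", decoy_mod_b = "adult_module",
              decoy_rare = "rare_variant")
  description <- c(
    planted_down = "planted downregulated-like set overlapping signal genes",
    decoy_up = "random decoy (upregulated-like)",
    decoy_mod_a = "random decoy co-expression module",
    decoy_mod_b = "random decoy co-expression module",
    decoy_rare = "random decoy rare-variant list")
  gene_sets <- gene_set_collection(sets, family = family,
                                   description = description)

  truth <- list(latent_factor = if (p$n_latent == 1L) drop(latent) else latent,
                signal_genes = signal_genes,
                planted_enriched_set_name = "planted_down",
                true_delta_ct = true_dct)

  structure(list(cohort = cohort, expression = expr, annotation = annotation,
                 gene_meta = gene_meta, gene_sets = gene_sets, truth = truth,
                 params = p),
            class = "synthetic_bundle")
}

#' Simulate a null bundle with no expression-thickness association
#'
#' Identical generative machinery to \code{\link{simulate_bundle}} but with
#' \code{latent_effect = 0} and \code{signal_loading = 0}: expression is pure
#' noise, the true regional difference is identically zero, and the reported
#' ground-truth signal-gene set is empty.  Used for calibration of permutation
#' tests and false-positive control.
#'
#' @inheritParams simulate_bundle
#' @return a \code{"synthetic_bundle"}.
#' @export
null_bundle <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  params$latent_effect <- 0
  params$signal_loading <- 0
  params$spatial_boost <- 0
  b <- simulate_bundle(params)
  b$truth$signal_genes <- character(0)
  b$truth$true_delta_ct[] <- 0
  b
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic bundle: %d regions x %d genes, %d subjects, seed %d\n",
              p$n_regions, p$n_genes, p$n_cases + p$n_controls, p$seed))
  cat(sprintf("  %d signal genes; planted set '%s' (%d genes); %d gene sets\n",
              length(x$truth$signal_genes), x$truth$planted_enriched_set_name,
              length(x$gene_sets$sets[[x$truth$planted_enriched_set_name]]),
              length(x$gene_sets$sets)))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes cohort, expression, annotation and gene metadata as TSV, gene sets
#' as GMT, and the ground truth as JSON, into \code{dir}.
#'
#' @param bundle a \code{"synthetic_bundle"}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             gene_meta = file.path(dir, "gene_meta.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_tsv(bundle$cohort, paths[["cohort"]])
  write_expression_tsv(bundle$expression, paths[["expression"]])
  write_tsv(bundle$annotation, paths[["annotation"]])
  write_tsv(bundle$gene_meta, paths[["gene_meta"]])
  write_gmt(bundle$gene_sets, paths[["gene_sets"]])
  truth <- bundle$truth
  truth$latent_factor <- unname(truth$latent_factor)
  truth$true_delta_ct <- as.list(truth$true_delta_ct)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate cell-type expression profiles
#'
#' Generates per-gene mean expression for five broad cortical cell classes
#' (neurons, astrocytes, oligodendrocytes, microglia, vascular cells) with a
#' random subset of genes markedly enriched in one class, for exercising
#' marker-set construction.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param markers_per_class number of planted marker genes per class.
#' @param seed RNG seed.
#' @return a data frame: gene_id plus one nonnegative expression column per
#'   cell class, with the planted marker assignment in
#'   \code{attr(, "marker_class")}.
#' @export
simulate_celltype_profiles <- function(gene_ids, markers_per_class = 100,
                                       seed = 1L) {
  classes <- c("neuron", "astrocyte", "oligodendrocyte", "microglia", "vascular")
  set.seed(seed)
  g <- length(gene_ids)
  base <- matrix(stats::rlnorm(g * length(classes), meanlog = 2, sdlog = 0.5),
                 g, length(classes), dimnames = list(gene_ids, classes))
  marker_class <- rep(NA_character_, g)
  pool <- sample(gene_ids, min(g, markers_per_class * length(classes)))
  assign <- split(pool, rep(classes, length.out = length(pool)))
  for (cl in classes) {
    idx <- match(assign[[cl]], gene_ids)
    base[idx, cl] <- base[idx, cl] * 8
    marker_class[idx] <- cl
  }
  out <- data.frame(gene_id = gene_ids, base, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "marker_class") <- stats::setNames(marker_class, gene_ids)
  out
}
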