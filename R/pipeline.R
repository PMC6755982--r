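# End-to-end orchestration: one config in, all stage outputs + manifest out.

.default_analysis <- function() {
  list(max_components = 35L, n_components = NULL, cv_folds = 10L,
       cv_repeats = 5L, b_perm = 10000L, n_boot = 1000L,
       z_threshold = 1.96, top_k = 200L, ve_b = 1000L, ve_alpha = 0.025,
       assoc_z_threshold = 1.96, scale_expression = TRUE,
       site_include_group = TRUE)
}

#' Assemble and validate a pipeline run configuration
#'
#' A run is driven either by simulation parameters (fully self-contained) or
#' by input file paths; analysis settings have full-scale defaults
#' (35-component search, 10,000 permutations, 1,000 bootstrap replicates,
#' z threshold 1.96, top-200 reporting, Von Economo q < 0.025) that can be
#' scaled down for desk-size runs.
#'
#' @param simulate \code{NULL}, or a list of \code{\link{simulation_params}}
#'   arguments.
#' @param inputs \code{NULL}, or a list of file paths: \code{cohort},
#'   \code{expression}, \code{annotation}, \code{gene_sets}, \code{gene_meta}.
#' @param analysis list overriding any default analysis setting (see above).
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param out_dir output directory for all stage outputs.
#' @return validated config list of class \code{"run_config"}.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, analysis = list(),
                       seed = 1L, out_dir = tempfile("ctpls_run_")) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of 'simulate' or 'inputs' must be given")
  if (!is.null(inputs)) {
    need <- c("cohort", "expression", "annotation", "gene_sets", "gene_meta")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs missing: ", paste(miss, collapse = ", "))
  }
  a <- utils::modifyList(.default_analysis(), analysis)
  for (nm in c("b_perm", "n_boot", "top_k", "ve_b", "max_components"))
    .assert_count(a[[nm]], nm)
  stopifnot(a$z_threshold > 0, a$ve_alpha > 0, a$ve_alpha < 1)
  structure(list(simulate = simulate, inputs = inputs, analysis = a,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}:
#' \code{simulate} or \code{inputs}, optional \code{analysis}, \code{seed},
#' \code{out_dir}.
#'
#' @param path YAML file path.
#' @param out_dir overrides the config's output directory when not NULL.
#' @return a \code{"run_config"}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  run_config(simulate = y$simulate, inputs = y$inputs,
             analysis = if (is.null(y$analysis)) list() else y$analysis,
             seed = if (is.null(y$seed)) 1L else y$seed,
             out_dir = if (!is.null(out_dir)) out_dir else
               if (is.null(y$out_dir)) tempfile("ctpls_run_") else y$out_dir)
}

.load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    pars <- config$simulate
    if (is.null(pars$seed)) pars$seed <- .stage_seed(config$seed, "simulate")
    bundle <- simulate_bundle(do.call(simulation_params, pars))
    list(cohort = bundle$cohort, expression = bundle$expression,
         annotation = bundle$annotation, gene_meta = bundle$gene_meta,
         gene_sets = bundle$gene_sets, truth = bundle$truth)
  } else {
    inp <- config$inputs
    expr <- read_expression_tsv(inp$expression)
    list(cohort = read_tsv(inp$cohort), expression = expr,
         annotation = read_tsv(inp$annotation),
         gene_meta = read_tsv(inp$gene_meta),
         gene_sets = read_gmt(inp$gene_sets), truth = NULL)
  }
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Executes, from one config: site-adjusted \eqn{\Delta CT}; region alignment;
#' cross-validated PLSR component selection; permutation test of explained
#' variance; bootstrap z-scoring of component-1 gene weights with FDR inverse
#' quantile transformation and significance selection; score-\eqn{\Delta CT}
#' correlation; Von Economo spatial characterization of the significant set;
#' and gene-length-adjusted gene-set enrichment (plus a thresholded
#' common-variant set from the gene-level association z-scores).  All stage
#' outputs are written as TSV into \code{config$out_dir} together with a
#' plain-text report and a JSON run manifest whose checksums make determinism
#' verifiable.
#'
#' @param config a \code{\link{run_config}}, or a YAML path accepted by
#'   \code{\link{read_run_config}}.
#' @return invisibly, a list with every stage result plus \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  a <- config$analysis
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  dat <- .load_inputs(config)
  if (!is.null(dat$truth)) {
    truth <- dat$truth
    truth$true_delta_ct <- as.list(truth$true_delta_ct)
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  # stage: delta CT
  adjusted <- regress_out_site(dat$cohort,
                               include_group = a$site_include_group)
  dct <- compute_delta_ct(adjusted)
  write_tsv(dct, out("delta_ct.tsv"))

  # stage: alignment
  al <- align_regions(dat$expression, dct, dat$annotation)
  x <- al$expression
  y <- al$delta_ct

  # stage: PLSR component selection + fit
  max_comp <- min(a$max_components, nrow(x) - ceiling(nrow(x) / a$cv_folds) - 1L,
                  ncol(x))
  cv <- select_n_components(x, y, max_components = max_comp,
                            folds = a$cv_folds, repeats = a$cv_repeats,
                            seed = .stage_seed(config$seed, "cv"),
                            scale. = a$scale_expression)
  ncomp <- if (!is.null(a$n_components)) as.integer(a$n_components) else
    max(1L, cv$ncomp)
  fit <- fit_plsr(x, y, ncomp = ncomp, scale. = a$scale_expression)
  perm <- permutation_test_components(x, y, ncomp = ncomp, B = a$b_perm,
                                      seed = .stage_seed(config$seed, "perm"),
                                      scale. = a$scale_expression)
  comp_tab <- data.frame(component = perm$component,
                         y_var_explained = perm$observed_variance,
                         p_perm = perm$p_perm)
  write_tsv(comp_tab, out("component_summary.tsv"))
  scores <- data.frame(region_id = rownames(fit$scores), fit$scores,
                       stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(scores, out("scores.tsv"))

  # stage: bootstrap weights + winner's-curse correction
  wt <- bootstrap_weights(x, y, component = 1L, n_boot = a$n_boot,
                          ncomp = ncomp,
                          seed = .stage_seed(config$seed, "boot"),
                          scale. = a$scale_expression)
  wt <- adjust_weight_table(wt, threshold = a$z_threshold)
  write_tsv(wt, out("gene_weights.tsv"))
  sig <- select_significant(wt, threshold = a$z_threshold)
  corr <- score_delta_correlation(fit, y, component = 1L)
  topk <- top_fraction_genes(wt, k = min(a$top_k, nrow(wt)))
  write_tsv(topk, out("top_genes.tsv"))

  # stage: spatial profile (needs a nonempty significant set)
  ve <- NULL
  if (length(sig) > 0) {
    ve <- ve_enrichment(x, al$annotation, sig, B = a$ve_b,
                        seed = .stage_seed(config$seed, "ve"),
                        alpha = a$ve_alpha)
    write_tsv(as.data.frame(ve), out("ve_profile.tsv"))
    set_score <- regional_set_score(x, sig)
    write_tsv(data.frame(region_id = names(set_score), score = set_score),
              out("set_score.tsv"))
  }

  # stage: gene-set enrichment
  enr <- NULL
  if (length(sig) > 0) {
    universe <- colnames(x)
    collection <- dat$gene_sets
    cv_set <- assoc_gene_set(dat$gene_meta, a$assoc_z_threshold)
    if (length(cv_set)) {
      collection$sets$common_variants <- cv_set
      collection$family["common_variants"] <- "common_variant"
      collection$description["common_variants"] <-
        sprintf("genes with association z >= %.3g", a$assoc_z_threshold)
    }
    enr <- enrich_families(sig, collection, universe,
                           covariates = dat$gene_meta)
    write_tsv(enrichment_table(enr), out("enrichment.tsv"))
  }

  results <- list(delta_ct = dct, alignment = al, cv = cv, fit = fit,
                  perm = perm, weights = wt, significant = sig,
                  correlation = corr, top_genes = topk, ve_profile = ve,
                  enrichment = enr, truth = dat$truth)
  report <- make_report(results, path = out("report.md"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctpls")),
    config = list(simulate = config$simulate, inputs = config$inputs,
                  analysis = a, seed = config$seed),
    derived_seeds = list(simulate = .stage_seed(config$seed, "simulate"),
                         cv = .stage_seed(config$seed, "cv"),
                         perm = .stage_seed(config$seed, "perm"),
                         boot = .stage_seed(config$seed, "boot"),
                         ve = .stage_seed(config$seed, "ve")),
    counts = list(n_regions = nrow(x), n_genes = ncol(x),
                  n_subjects = length(unique(dat$cohort$subject_id)),
                  n_components = ncomp,
                  n_dropped_regions = unname(al$n_dropped),
                  n_significant_genes = length(sig)),
    outputs = as.list(tools::md5sum(
      sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                   out("manifest.json"))))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Enrichment results in standard report layout
#'
#' Reorders an \code{\link{enrich_families}} result into the conventional
#' report columns: Category, Dataset, OR, Upper CI (95\%), Lower CI (95\%),
#' P, P_corrected.
#'
#' @param enr an \code{"enrichment_result"} from \code{\link{enrich_families}}.
#' @return data frame in report column order.
#' @export
enrichment_table <- function(enr) {
  stopifnot(is.data.frame(enr))
  data.frame(Category = enr$family, Dataset = enr$set_name,
             OR = enr$or_estimate, `Upper CI (95%)` = enr$ci_high,
             `Lower CI (95%)` = enr$ci_low, P = enr$p, P_corrected = enr$q,
             check.names = FALSE)
}

.fmt_tab <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  c(paste(names(df), collapse = " | "),
    paste(rep("---", ncol(df)), collapse = " | "),
    apply(df, 1L, paste, collapse = " | "))
}

#' Render a plain-text analysis report
#'
#' Writes a markdown report from pipeline stage results: component
#' variance/permutation table, score-\eqn{\Delta CT} correlation, significant
#' gene count, top-gene table, Von Economo profile and the enrichment table.
#' Stages absent from \code{results} render as explicit absent sections, so a
#' partial run still reports.  Regeneration from the same results is
#' byte-identical.
#'
#' @param results list as produced by \code{\link{run_pipeline}}.
#' @param path output file.
#' @param top_n rows of the top-gene table to print.
#' @return invisibly, the report lines.
#' @export
make_report <- function(results, path, top_n = 20L) {
  L <- c("# Imaging-transcriptomics PLSR report", "")
  absent <- function(what) c(paste0("## ", what), "", "(section absent)", "")
  if (!is.null(results$perm)) {
    L <- c(L, "## Components", "",
           .fmt_tab(data.frame(component = results$perm$component,
                               y_var_explained = results$perm$observed_variance,
                               p_perm = results$perm$p_perm)), "")
  } else L <- c(L, absent("Components"))
  if (!is.null(results$correlation)) {
    L <- c(L, "## Component 1 score vs deltaCT", "",
           sprintf("Pearson r = %.4g, p = %.4g", results$correlation$r,
                   results$correlation$p), "")
  } else L <- c(L, absent("Component 1 score vs deltaCT"))
  if (!is.null(results$weights)) {
    nsig <- length(results$significant)
    L <- c(L, "## Significant genes", "",
           sprintf("%d significant genes (|z_fiqt| above threshold) out of %d.",
                   nsig, nrow(results$weights)), "")
    if (!is.null(results$top_genes)) {
      tk <- utils::head(results$top_genes, top_n)
      L <- c(L, sprintf("Top %d genes by |z_fiqt|:", nrow(tk)), "",
             .fmt_tab(tk[c("gene_id", "weight", "z", "z_fiqt")]), "")
    }
  } else L <- c(L, absent("Significant genes"))
  if (!is.null(results$ve_profile)) {
    L <- c(L, "## Von Economo spatial profile", "",
           .fmt_tab(as.data.frame(results$ve_profile)[
             c("ve_class", "observed_mean", "z", "p_perm", "q", "direction")]),
           "")
  } else L <- c(L, absent("Von Economo spatial profile"))
  if (!is.null(results$enrichment)) {
    L <- c(L, "## Gene-set enrichment", "",
           .fmt_tab(enrichment_table(results$enrichment)), "")
  } else L <- c(L, absent("Gene-set enrichment"))
  writeLines(L, path)
  invisible(L)
}

#' Sensitivity and false-positive rate against planted ground truth
#'
#' Convenience scorer for synthetic runs: fraction of planted signal genes
#' recovered in the selected set, and fraction of selected genes that are not
#' signal (observed false-discovery proportion), plus the false-positive rate
#' among non-signal genes.
#'
#' @param selected character vector of selected gene ids.
#' @param truth the \code{truth} element of a \code{"synthetic_bundle"}.
#' @param universe measured-gene universe.
#' @return list: sensitivity, fdp, fpr, n_selected.
#' @export
evaluate_recovery <- function(selected, truth, universe) {
  signal <- intersect(truth$signal_genes, universe)
  nonsignal <- setdiff(universe, signal)
  list(sensitivity = if (length(signal)) mean(signal %in% selected) else NA_real_,
       fdp = if (length(selected)) mean(!selected %in% signal) else 0,
       fpr = mean(nonsignal %in% selected),
       n_selected = length(selected))
}
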