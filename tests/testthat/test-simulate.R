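test_that("identical parameters and seed reproduce the bundle exactly", {
  p <- simulation_params(n_regions = 20, n_genes = 50, n_cases = 8,
                         n_controls = 8, seed = 42)
  expect_identical(simulate_bundle(p), simulate_bundle(p))
})

test_that("zero-noise bundles reproduce the true difference exactly", {
  b <- simulate_bundle(simulation_params(
    n_regions = 15, n_genes = 40, n_cases = 6, n_controls = 6, n_sites = 1,
    noise_sd_ct = 0, site_effect_sd = 0, seed = 3))
  dct <- compute_delta_ct(b$cohort)
  expect_equal(setNames(dct$delta_ct, dct$region_id),
               b$truth$true_delta_ct[dct$region_id])
})

test_that("invalid parameters are rejected", {
  expect_error(simulation_params(signal_gene_count = 60, n_genes = 50),
               "signal_gene_count")
  expect_error(simulation_params(n_cases = 3, n_controls = 3, n_sites = 10),
               "n_sites")
  expect_error(simulation_params(planted_set_overlap = 1.2), "planted_set_overlap")
  expect_error(simulation_params(noise_sd_ct = -1), "noise_sd_ct")
})

test_that("null bundles carry no signal and an empty truth set", {
  b <- cached_bundle(n_regions = 30, n_genes = 60, n_cases = 8, n_controls = 8,
                     seed = 5, null = TRUE)
  expect_identical(b$truth$signal_genes, character(0))
  expect_true(all(b$truth$true_delta_ct == 0))
  # expression is pure noise with the requested SD (>= 1e5 draws elsewhere;
  # here just check the mean structure is absent)
  expect_lt(abs(mean(b$expression)), 0.05)
})

test_that("expression noise SD matches the requested level within 10%", {
  b <- cached_bundle(n_regions = 60, n_genes = 2000, n_cases = 4,
                     n_controls = 4, seed = 8, null = TRUE)
  expect_lt(abs(sd(b$expression) - b$params$noise_sd_expression) /
              b$params$noise_sd_expression, 0.10)
})

test_that("planted set overlaps signal genes by the configured fraction", {
  b <- simulate_bundle(simulation_params(
    n_regions = 20, n_genes = 200, n_cases = 5, n_controls = 5,
    signal_gene_count = 50, planted_set_size = 40, planted_set_overlap = 0.5,
    seed = 2))
  planted <- b$gene_sets$sets[[b$truth$planted_enriched_set_name]]
  expect_length(planted, 40)
  expect_identical(sum(planted %in% b$truth$signal_genes), 20L)
})

test_that("bundle identifiers agree across components", {
  b <- small_bundle()
  expect_setequal(unique(b$cohort$region_id), rownames(b$expression))
  expect_identical(b$annotation$region_id, rownames(b$expression))
  expect_identical(b$gene_meta$gene_id, colnames(b$expression))
  expect_true(all(unlist(b$gene_sets$sets) %in% colnames(b$expression)))
  expect_true(all(b$truth$signal_genes %in% colnames(b$expression)))
})

test_that("bundles round-trip through plain-text files", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(read_expression_tsv(paths[["expression"]]), b$expression,
               tolerance = 1e-12)
  back <- read_gmt(paths[["gene_sets"]])
  expect_identical(back$sets, b$gene_sets$sets)
  cohort <- read_tsv(paths[["cohort"]])
  expect_equal(cohort$thickness, b$cohort$thickness, tolerance = 1e-12)
})

test_that("pipeline sensitivity is non-decreasing in the signal loading", {
  sens <- sapply(c(0.25, 0.5, 1.0), function(load) {
    mean(sapply(1:10, function(s) {
      b <- cached_bundle(n_regions = 40, n_genes = 300, n_cases = 20,
                         n_controls = 20, n_sites = 2, signal_gene_count = 30,
                         signal_loading = load, seed = 200 + s)
      al <- aligned_data(b)
      wt <- bootstrap_weights(al$expression, al$delta_ct, n_boot = 100,
                              seed = s)
      sig <- select_significant(adjust_weight_table(wt))
      evaluate_recovery(sig, b$truth, colnames(al$expression))$sensitivity
    }))
  })
  expect_true(all(diff(sens) >= 0))
})

test_that("synthetic cell-type profiles plant recoverable markers", {
  genes <- sprintf("G%04d", 1:400)
  prof <- simulate_celltype_profiles(genes, markers_per_class = 20, seed = 4)
  expect_true(all(as.matrix(prof[-1]) > 0))
  marker <- attr(prof, "marker_class")
  sets <- build_celltype_sets(prof, top_n = 20)
  neurons <- names(marker)[!is.na(marker) & marker == "neuron"]
  expect_gte(mean(neurons %in% sets$sets$neuron), 0.9)
})
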