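test_that("cross-validation prefers a small model for one planted factor", {
  b <- cached_bundle(n_regions = 40, n_genes = 120, n_cases = 25,
                     n_controls = 25, signal_gene_count = 30,
                     noise_sd_ct = 0.05, noise_sd_expression = 0.1, seed = 21)
  al <- aligned_data(b)
  cv <- select_n_components(al$expression, al$delta_ct, max_components = 8,
                            folds = 5, repeats = 2, seed = 1)
  expect_lte(cv$ncomp, 3)
  expect_gte(cv$ncomp, 1)
  # one component beats the mean-only baseline decisively
  expect_lt(cv$cv_error[["1"]], 0.5 * cv$cv_error[["0"]])
})

test_that("cross-validation finds no structure in null bundles", {
  better <- sapply(1:10, function(s) {
    b <- cached_bundle(n_regions = 30, n_genes = 80, n_cases = 10,
                       n_controls = 10, seed = 400 + s, null = TRUE)
    al <- aligned_data(b)
    cv <- select_n_components(al$expression, al$delta_ct, max_components = 5,
                              folds = 5, repeats = 1, seed = s)
    min(cv$cv_error[-1]) < 0.95 * cv$cv_error[["0"]]
  })
  expect_lte(mean(better), 0.5)
})

test_that("fewer regions than folds is an error", {
  inst <- matrix(rnorm(40), 4, 10)
  expect_error(select_n_components(inst, rnorm(4), folds = 10),
               "fewer regions")
})

test_that("permutation p attains its add-one lower bound on strong signal", {
  b <- cached_bundle(n_regions = 40, n_genes = 60, n_cases = 30,
                     n_controls = 30, signal_gene_count = 40,
                     signal_loading = 3, noise_sd_expression = 0.1,
                     noise_sd_ct = 0.1, seed = 31)
  al <- aligned_data(b)
  perm <- permutation_test_components(al$expression, al$delta_ct, ncomp = 1,
                                      B = 199, seed = 2)
  expect_equal(perm$p_perm[1], 1 / 200)
  expect_identical(dim(attr(perm, "null_variances")), c(199L, 1L))
})

test_that("permutation results are reproducible under the seed", {
  b <- small_bundle()
  al <- aligned_data(b)
  p1 <- permutation_test_components(al$expression, al$delta_ct, B = 49, seed = 7)
  p2 <- permutation_test_components(al$expression, al$delta_ct, B = 49, seed = 7)
  expect_identical(p1, p2)
})

test_that("negating the response flips weights but not bootstrap |z|", {
  b <- small_bundle()
  al <- aligned_data(b)
  w1 <- bootstrap_weights(al$expression, al$delta_ct, n_boot = 100, seed = 5)
  w2 <- bootstrap_weights(al$expression, -al$delta_ct, n_boot = 100, seed = 5)
  expect_equal(w2$weight, -w1$weight, tolerance = 1e-12)
  expect_equal(abs(w2$z), abs(w1$z), tolerance = 1e-12)
})

test_that("signal genes dominate the bootstrap z ranking without noise", {
  b <- cached_bundle(n_regions = 30, n_genes = 80, n_cases = 10,
                     n_controls = 10, n_sites = 1, signal_gene_count = 20,
                     noise_sd_expression = 1e-4, noise_sd_ct = 0,
                     site_effect_sd = 0, seed = 17)
  al <- aligned_data(b)
  wt <- bootstrap_weights(al$expression, al$delta_ct, n_boot = 500, seed = 1)
  is_sig <- wt$gene_id %in% b$truth$signal_genes
  expect_gt(min(abs(wt$z[is_sig])), max(abs(wt$z[!is_sig])))
})

test_that("bootstrap SE stabilizes as replicates double", {
  b <- small_bundle()
  al <- aligned_data(b)
  w500 <- bootstrap_weights(al$expression, al$delta_ct, n_boot = 500, seed = 3)
  w1000 <- bootstrap_weights(al$expression, al$delta_ct, n_boot = 1000, seed = 4)
  rel <- abs(w1000$se_boot - w500$se_boot) / w500$se_boot
  expect_gte(mean(rel < 0.10), 0.95)
})

test_that("FIQT shrinks magnitudes, keeps order and handles edge cases", {
  expect_equal(fiqt_adjust(2.5), 2.5)
  expect_equal(fiqt_adjust(rep(1.7, 5)), rep(1.7, 5))
  set.seed(8)
  for (i in 1:20) {
    z <- rnorm(sample(5:50, 1), sd = 2)
    zf <- fiqt_adjust(z)
    expect_true(all(abs(zf) <= abs(z) + 1e-12))
    # monotone in |z| (BH can tie neighbours, so non-strict)
    expect_true(all(diff(abs(zf)[order(abs(z))]) >= -1e-12))
    expect_identical(sign(zf)[zf != 0], sign(z)[zf != 0])
  }
  expect_error(fiqt_adjust(c(1, NA)), "finite")
})

test_that("significant-gene selection uses the unsigned corrected z", {
  tab <- data.frame(gene_id = c("A", "B", "C"), weight = c(-1, 1, 0.1),
                    se_boot = 1, z = c(-3, 3, 1),
                    z_fiqt = c(-2.5, 2.5, 1.0))
  expect_identical(select_significant(tab), c("A", "B"))
  tab$z_fiqt <- 0
  expect_identical(select_significant(tab), character(0))
})

test_that("adjust_weight_table applies the 1.96 default consistently", {
  b <- small_bundle()
  al <- aligned_data(b)
  wt <- adjust_weight_table(
    bootstrap_weights(al$expression, al$delta_ct, n_boot = 100, seed = 2))
  expect_identical(wt$significant, abs(wt$z_fiqt) > 1.96)
  expect_setequal(select_significant(wt), wt$gene_id[wt$significant])
})

test_that("top-gene ranking is deterministic with documented tie-breaks", {
  tab <- data.frame(gene_id = c("B", "A", "C", "D"),
                    weight = c(1, 1, 2, 0.5), se_boot = 1,
                    z = c(2, 2, 2, 1), z_fiqt = c(1.5, 1.5, 1.5, 0.9))
  top <- top_fraction_genes(tab, k = 4)
  expect_identical(top$gene_id, c("C", "A", "B", "D"))
  expect_identical(top_fraction_genes(tab, k = 2)$gene_id, c("C", "A"))
  expect_error(top_fraction_genes(tab, k = 5), "exceeds")
})

test_that("component-1 scores track the response on clean planted data", {
  # zero noise everywhere: non-signal genes are constant and dropped, the
  # remaining columns are all exact copies of the latent factor
  b <- cached_bundle(n_regions = 30, n_genes = 80, n_cases = 10,
                     n_controls = 10, n_sites = 1, signal_gene_count = 20,
                     noise_sd_expression = 0, noise_sd_ct = 0,
                     site_effect_sd = 0, seed = 17)
  al <- aligned_data(b)
  fit <- suppressMessages(fit_plsr(al$expression, al$delta_ct, ncomp = 1))
  sc <- score_delta_correlation(fit)
  expect_equal(abs(sc$r), 1, tolerance = 1e-6)
  expect_lt(sc$p, 1e-20)
})
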