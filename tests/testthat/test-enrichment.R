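make_universe <- function(n) sprintf("g%04d", seq_len(n))

test_that("logistic OR reduces to the 2x2 cross-product ratio", {
  # worked case: universe 100, target 20, candidate 30, overlap 10
  u <- make_universe(100)
  target <- u[1:20]
  candidate <- c(u[1:10], u[21:40])
  covs <- data.frame(gene_id = u, length_bp = 1000)  # constant covariate
  r <- logistic_enrichment(target, candidate, u, covs)
  expect_equal(r$or_estimate, 3.0, tolerance = 1e-6)
  expect_identical(r$n_overlap, 10L)
  expect_false(r$corrected)
  # CI brackets the estimate
  expect_lt(r$ci_low, r$or_estimate)
  expect_gt(r$ci_high, r$or_estimate)
})

test_that("logistic OR matches the marginal table on random instances", {
  set.seed(31)
  for (i in 1:20) {
    u <- make_universe(sample(80:200, 1))
    target <- sample(u, sample(10:30, 1))
    candidate <- sample(u, sample(10:40, 1))
    tab <- table(factor(u %in% target, c(TRUE, FALSE)),
                 factor(u %in% candidate, c(TRUE, FALSE)))
    if (any(tab == 0)) next
    oracle <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    r <- logistic_enrichment(target, candidate, u)
    expect_equal(r$or_estimate, unname(oracle), tolerance = 1e-6)
  }
})

test_that("enrichment is symmetric in target and candidate without covariates", {
  set.seed(5)
  u <- make_universe(150)
  a <- sample(u, 40); b <- sample(u, 25)
  expect_equal(logistic_enrichment(a, b, u)$or_estimate,
               logistic_enrichment(b, a, u)$or_estimate, tolerance = 1e-6)
})

test_that("empty 2x2 cells fall back to the flagged Haldane correction", {
  u <- make_universe(60)
  target <- u[1:10]
  candidate <- u[11:20]  # zero overlap
  r <- logistic_enrichment(target, candidate, u)
  expect_true(r$corrected)
  expect_identical(r$n_overlap, 0L)
  expect_equal(r$or_estimate, (0.5 * 40.5) / (10.5 * 10.5), tolerance = 1e-10)
})

test_that("gene-length adjustment removes planted length confounding", {
  set.seed(77)
  closer <- replicate(50, {
    u <- make_universe(400)
    len <- rlnorm(400, 9, 1)
    # membership in both sets driven by length (common cause, no direct link)
    p_t <- plogis(scale(log(len))[, 1] - 1.2)
    p_c <- plogis(scale(log(len))[, 1] - 1.2)
    target <- u[runif(400) < p_t]
    candidate <- u[runif(400) < p_c]
    if (length(target) < 5 || length(candidate) < 5) return(NA)
    covs <- data.frame(gene_id = u, length_bp = len)
    raw <- logistic_enrichment(target, candidate, u)
    adj <- logistic_enrichment(target, candidate, u, covs)
    if (raw$corrected || adj$corrected) return(NA)
    abs(log(adj$or_estimate)) < abs(log(raw$or_estimate))
  })
  expect_gte(mean(closer, na.rm = TRUE), 0.75)
})

test_that("family-wise adjustment uses BH except Bonferroni for cell types", {
  u <- make_universe(300)
  set.seed(9)
  sets <- list(s1 = sample(u, 40), s2 = sample(u, 40), s3 = sample(u, 40),
               n1 = sample(u, 50), n2 = sample(u, 50))
  fam <- c(s1 = "dysregulated", s2 = "dysregulated", s3 = "dysregulated",
           n1 = "cell_type", n2 = "cell_type")
  coll <- gene_set_collection(sets, family = fam)
  target <- sample(u, 60)
  res <- enrich_families(target, coll, u)
  d <- res[res$family == "dysregulated", ]
  expect_equal(d$q, p.adjust(d$p, "BH"))
  ct <- res[res$family == "cell_type", ]
  expect_equal(ct$q, p.adjust(ct$p, "bonferroni"))
  expect_identical(res$enriched, res$q < 0.05 & res$or_estimate > 1)
})

test_that("a single-set family keeps q equal to p; duplicates share results", {
  u <- make_universe(200)
  set.seed(4)
  s <- sample(u, 30)
  coll <- gene_set_collection(list(only = s),
                              family = c(only = "rare_variant"))
  res <- enrich_families(sample(u, 50), coll, u)
  expect_equal(res$q, res$p)

  coll2 <- gene_set_collection(list(a = s, b = s),
                               family = c(a = "rare_variant", b = "rare_variant"))
  res2 <- enrich_families(sample(u, 50), coll2, u)
  expect_equal(res2$or_estimate[1], res2$or_estimate[2])
  expect_equal(res2$p[1], res2$p[2])
  expect_equal(res2$q, p.adjust(res2$p, "BH"))
})

test_that("a set outside the universe yields a flagged zero-overlap result", {
  u <- make_universe(100)
  coll <- gene_set_collection(list(alien = c("x1", "x2", "x3")),
                              family = c(alien = "dysregulated"))
  res <- enrich_families(u[1:20], coll, u)
  expect_identical(res$n_overlap, 0L)
  expect_true(res$corrected)
})

test_that("cell-type marker sets rank by fold-difference deterministically", {
  genes <- sprintf("g%03d", 1:50)
  prof <- data.frame(gene_id = genes,
                     neuron = 1, astrocyte = 1, oligodendrocyte = 1,
                     microglia = 1, vascular = 1)
  prof$neuron[prof$gene_id == "g007"] <- 100  # expressed only in neurons
  sets <- build_celltype_sets(prof, top_n = 5)
  expect_true("g007" %in% sets$sets$neuron)
  expect_identical(unname(sets$family["neuron"]), "cell_type")
  # order invariance
  sets2 <- build_celltype_sets(prof[rev(seq_len(nrow(prof))), ], top_n = 5)
  expect_identical(sets$sets, sets2$sets)
  expect_error(build_celltype_sets(prof, top_n = 51), "exceeds")
})

test_that("hypergeometric over-representation matches brute-force summation", {
  u <- make_universe(1000)
  set.seed(13)
  pathway <- sample(u, 50)
  target <- c(sample(pathway, 8), sample(setdiff(u, pathway), 42))
  coll <- gene_set_collection(list(p1 = pathway), family = c(p1 = "pathway"))
  res <- over_representation(target, coll, u)
  # oracle: direct summation of the hypergeometric pmf over the upper tail
  brute <- sum(sapply(8:50, function(k)
    choose(50, k) * choose(950, 50 - k) / choose(1000, 50)))
  expect_equal(res$p, brute, tolerance = 1e-12)

  disjoint <- gene_set_collection(list(p = setdiff(u, target)[1:30]),
                                  family = c(p = "pathway"))
  expect_equal(over_representation(target, disjoint, u)$p, 1)
  whole <- gene_set_collection(list(p = u), family = c(p = "pathway"))
  expect_equal(over_representation(target, whole, u)$p, 1)
  expect_error(over_representation(character(0), coll, u), "empty")
})

test_that("association z-scores threshold into a candidate set", {
  meta <- data.frame(gene_id = c("a", "b", "c", "d"),
                     assoc_z = c(2.5, 1.0, -3, 1.96))
  expect_identical(assoc_gene_set(meta), c("a", "d"))
  expect_identical(assoc_gene_set(meta, z_threshold = 2), "a")
})
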