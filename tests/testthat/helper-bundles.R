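# Shared fixtures, built in code.  Bundles are memoised per option string so
# repeated tests do not pay simulation cost twice.

.bundle_cache <- new.env(parent = emptyenv())

cached_bundle <- function(..., null = FALSE) {
  key <- paste(deparse(list(...)), null, collapse = "")
  if (is.null(.bundle_cache[[key]])) {
    p <- simulation_params(...)
    .bundle_cache[[key]] <- if (null) null_bundle(p) else simulate_bundle(p)
  }
  .bundle_cache[[key]]
}

# a small, fast planted bundle for unit tests
small_bundle <- function(seed = 1) {
  cached_bundle(n_regions = 40, n_genes = 300, n_cases = 20, n_controls = 20,
                n_sites = 2, signal_gene_count = 30, planted_set_size = 30,
                seed = seed)
}

# delta-CT + aligned expression for a bundle
aligned_data <- function(bundle) {
  dct <- compute_delta_ct(suppressWarnings(regress_out_site(bundle$cohort)))
  suppressMessages(align_regions(bundle$expression, dct, bundle$annotation))
}

# tiny deterministic cohort: two groups, optional sites, zero noise
toy_cohort <- function(n_per_group = 4, regions = c("A", "B"), delta = 0.1,
                       sites = NULL, site_offsets = NULL, baseline = 2.5) {
  n <- 2 * n_per_group
  group <- rep(c("case", "control"), each = n_per_group)
  site <- if (is.null(sites)) rep("S1", n) else rep_len(sites, n)
  grid <- expand.grid(i = seq_len(n), region_id = regions,
                      stringsAsFactors = FALSE)
  th <- baseline + delta * as.numeric(group[grid$i] == "case")
  if (!is.null(site_offsets)) th <- th + site_offsets[site[grid$i]]
  data.frame(subject_id = sprintf("s%02d", grid$i),
             group = group[grid$i], site = site[grid$i],
             region_id = grid$region_id, thickness = th,
             stringsAsFactors = FALSE)
}
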