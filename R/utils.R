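#' @keywords internal
"_PACKAGE"

# --- small shared helpers -----------------------------------------------------

# stage seeds are derived additively from one master seed so every stochastic
# stage has its own reproducible stream; offsets are part of the package contract
# and recorded in the run manifest.
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, cv = 1L, perm = 2L, boot = 3L, ve = 4L, report = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  s <- as.double(seed) + as.double(offsets[[stage]])
  if (s >= 2^31 - 1) s <- s - 2^31 + 7
  as.integer(s)
}

.assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

.assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
  invisible(as.numeric(x))
}

.assert_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop("'", name, "' must be a single non-negative number", call. = FALSE)
  invisible(as.numeric(x))
}

# center/scale a predictor matrix; zero-variance columns become all-zero
# instead of NaN so resampled design matrices never poison downstream algebra.
.standardize <- function(x, scale. = TRUE) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  if (scale.) {
    sds <- sqrt(colSums(xc^2) / (nrow(x) - 1L))
    zero <- sds <= 0 | !is.finite(sds)
    sds[zero] <- 1
    xc <- sweep(xc, 2L, sds, "/")
    if (any(zero)) xc[, zero] <- 0
  } else {
    sds <- rep(1, ncol(x))
    zero <- rep(FALSE, ncol(x))
  }
  list(x = xc, center = ctr, scale = sds, zero_var = zero)
}

# write a data.frame as TSV with stable formatting (no quoting, no rownames)
# so repeated runs of the same analysis are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
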