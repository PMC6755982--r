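# Case-control cortical thickness differences with scanner-site adjustment.

.check_cohort <- function(cohort) {
  need <- c("subject_id", "group", "site", "region_id", "thickness")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$group %in% c("case", "control")))
    stop("cohort$group must be 'case' or 'control'")
  if (any(!is.finite(cohort$thickness)))
    stop("cohort$thickness must be finite")
  invisible(cohort)
}

#' Regress scanner site out of regional thickness estimates
#'
#' Per region, a linear model of thickness on scanner-site indicators is
#' fitted -- with group as a covariate by default, so the case-control signal
#' is not absorbed into the site coefficients when sites differ in
#' case/control composition -- and the fitted site contribution, centered
#' across subjects, is removed.  Equivalently, each subject keeps the residual
#' of the site term re-added to its model-based mean, so adjusted values stay
#' interpretable in mm, the regional grand mean is unchanged, and only
#' between-site offsets are removed from the group contrast.
#'
#' A cohort measured at a single site is returned unchanged.  A site whose
#' subjects all belong to one group triggers a warning (site and group are
#' confounded there; the group covariate then carries the overlap).
#'
#' @param cohort long-format data frame with columns subject_id, group
#'   (\code{"case"}/\code{"control"}), site, region_id, thickness (mm).
#' @param include_group include group in the site model (default \code{TRUE}).
#' @param per_region fit the site model separately per region (default) or
#'   pooled across regions.
#' @return the cohort with adjusted \code{thickness}.
#' @export
regress_out_site <- function(cohort, include_group = TRUE, per_region = TRUE) {
  .check_cohort(cohort)
  sites <- unique(cohort$site)
  if (length(sites) <= 1L) return(cohort)

  tab <- table(unique(cohort[c("subject_id", "group", "site")])[c("site", "group")])
  confounded <- rownames(tab)[apply(tab > 0, 1L, sum) < 2L]
  if (length(confounded))
    warning("site(s) with all subjects in one group (site/group confounded): ",
            paste(confounded, collapse = ", "))

  form <- if (include_group) thickness ~ site + group else thickness ~ site
  adjust_block <- function(d) {
    fit <- stats::lm(form, data = d)
    mm <- stats::model.matrix(fit)
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0  # aliased terms (fully confounded designs)
    site_cols <- grep("^site", colnames(mm), value = TRUE)
    site_part <- drop(mm[, site_cols, drop = FALSE] %*% beta[site_cols])
    d$thickness <- d$thickness - (site_part - mean(site_part))
    d
  }
  if (per_region) {
    parts <- split(cohort, cohort$region_id)
    cohort <- unsplit(lapply(parts, adjust_block), cohort$region_id)
  } else {
    cohort <- adjust_block(cohort)
  }
  cohort
}

#' Compute the per-region case-control thickness difference
#'
#' \eqn{\Delta CT_r} = mean case thickness at region \eqn{r} minus mean
#' control thickness, typically computed on a site-adjusted cohort (see
#' \code{\link{regress_out_site}}).
#'
#' @param cohort long-format cohort (ideally site-adjusted).
#' @return data frame with columns \code{region_id} and \code{delta_ct} (mm),
#'   one row per region, ordered by region_id.
#' @export
compute_delta_ct <- function(cohort) {
  .check_cohort(cohort)
  agg <- stats::aggregate(thickness ~ region_id + group, data = cohort,
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "region_id", timevar = "group",
                         direction = "wide")
  bad <- wide$region_id[!stats::complete.cases(wide)]
  if (length(bad))
    stop("region(s) missing one group: ", paste(sort(bad), collapse = ", "))
  out <- data.frame(region_id = wide$region_id,
                    delta_ct = wide$thickness.case - wide$thickness.control,
                    stringsAsFactors = FALSE)
  out[order(out$region_id), , drop = FALSE]
}
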