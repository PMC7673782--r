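# Replicate-aware differential comparisons between genotypes.
#
# The unit of replication is the mouse: each mouse contributes one per-site
# frequency (or one isoform proportion) and groups are compared with
# Student's t-test, falling back to the Mann-Whitney test when either group
# fails a Shapiro-Wilk normality check — the test-selection policy applied
# throughout.  Read-level tests would be wildly anticonfident and are not
# offered.

#' Choose between Student's t-test and Mann-Whitney
#'
#' Applies a Shapiro-Wilk check at \code{alpha_norm} to each group and
#' selects the t-test iff both pass.  Groups with fewer than 3 values
#' cannot be checked and default to Mann-Whitney, as do constant groups
#' (with a warning).
#'
#' @param x,y Numeric vectors (one value per replicate).
#' @param alpha_norm Significance level of the normality check.
#' @return \code{"t_test"} or \code{"mann_whitney"}.
#' @export
normality_gate <- function(x, y, alpha_norm = 0.05) {
  if (length(x) < 3 || length(y) < 3) return("mann_whitney")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant group; falling back to Mann-Whitney")
    return("mann_whitney")
  }
  p1 <- stats::shapiro.test(x)$p.value
  p2 <- stats::shapiro.test(y)$p.value
  if (p1 > alpha_norm && p2 > alpha_norm) "t_test" else "mann_whitney"
}

#' Two-group comparison with the normality-gated test
#'
#' Mann-Whitney p-values use the exact distribution when the combined
#' sample size is at most 20 and there are no ties, and otherwise the
#' normal approximation with tie correction.  Two identical groups give
#' p = 1 by convention (complete ties carry no evidence).
#'
#' @param x,y Numeric vectors.
#' @param alpha_norm Normality-check level passed to [normality_gate()].
#' @return List with \code{p} and \code{test}.
#' @export
gated_test <- function(x, y, alpha_norm = 0.05) {
  test <- suppressWarnings(normality_gate(x, y, alpha_norm))
  if (test == "t_test") {
    p <- stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    all_vals <- c(x, y)
    if (length(unique(all_vals)) == 1 ||
        (length(x) == length(y) && all(sort(x) == sort(y)))) {
      # the groups are indistinguishable; complete ties carry no evidence
      p <- 1
    } else {
      exact <- length(all_vals) <= 20 && !anyDuplicated(all_vals)
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    }
  }
  list(p = p, test = test)
}

.split_groups <- function(values, genotype, ref_group, alt_group) {
  list(wt = values[genotype == ref_group], ko = values[genotype == alt_group])
}

#' Compare per-site editing frequencies between genotypes
#'
#' Each mouse contributes one frequency per site; per region and site the
#' two genotypes are compared with the gated test.  The difference is
#' reported as KO mean minus WT mean, in percentage points.  Samples with a
#' missing (NA) frequency at a site are excluded from that site with a
#' warning.
#'
#' @param site_df Long table from [site_table()] (or
#'   [simulate_cohort_frequencies()]): columns \code{sample},
#'   \code{genotype}, \code{region}, \code{site}, \code{pct}.
#' @param alpha Significance level for the \code{significant} flag.
#' @param ref_group,alt_group Genotype labels (defaults WT vs KO).
#' @return Data.frame: \code{region}, \code{site}, \code{mean_wt},
#'   \code{mean_ko}, \code{difference} (pp), \code{p}, \code{test},
#'   \code{significant}.
#' @export
compare_sites <- function(site_df, alpha = 0.05,
                          ref_group = "WT", alt_group = "KO") {
  stopifnot(all(c("genotype", "region", "site", "pct") %in% names(site_df)))
  for (g in c(ref_group, alt_group))
    if (!any(site_df$genotype == g))
      stop("genotype '", g, "' absent from the table")
  combos <- unique(site_df[, c("region", "site")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- site_df$region == combos$region[i] & site_df$site == combos$site[i]
    d <- site_df[sel, ]
    if (anyNA(d$pct)) {
      warning(sprintf("site %s (%s): excluding %d sample(s) with missing frequency",
                      combos$site[i], combos$region[i], sum(is.na(d$pct))))
      d <- d[!is.na(d$pct), ]
    }
    g <- .split_groups(d$pct, d$genotype, ref_group, alt_group)
    res <- gated_test(g$wt, g$ko)
    data.frame(region = combos$region[i], site = combos$site[i],
               mean_wt = mean(g$wt), mean_ko = mean(g$ko),
               difference = mean(g$ko) - mean(g$wt),
               p = res$p, test = res$test,
               significant = res$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$region, match(out$site, .SITES_DISPLAY)), ]
}

#' Compare isoform proportions between genotypes
#'
#' Per region and editing pattern, the per-mouse proportions (percent of
#' complete reads) are compared with the gated test.  The ratio is the
#' KO group mean over the WT group mean, and rows whose WT abundance falls
#' below \code{low_abundance_pct} are flagged as lowly expressed.
#' Patterns absent in every sample of a region are omitted (with a
#' message).
#'
#' @param iso_df Long table from [isoform_table()]: columns \code{sample},
#'   \code{genotype}, \code{region}, \code{pattern}, \code{pct}.
#' @param alpha Significance level for the \code{significant} flag.
#' @param low_abundance_pct Threshold (percent of total) below which a WT
#'   isoform is flagged as lowly expressed (default 5).
#' @param ref_group,alt_group Genotype labels.
#' @return Data.frame: \code{region}, \code{pattern}, \code{wt_mean_pct},
#'   \code{ko_mean_pct}, \code{ko_wt_ratio}, \code{p}, \code{test},
#'   \code{significant}, \code{low_abundance}.
#' @export
compare_isoforms <- function(iso_df, alpha = 0.05, low_abundance_pct = 5,
                             ref_group = "WT", alt_group = "KO") {
  stopifnot(all(c("genotype", "region", "pattern", "pct") %in% names(iso_df)))
  combos <- unique(iso_df[, c("region", "pattern")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- iso_df$region == combos$region[i] &
      iso_df$pattern == combos$pattern[i]
    d <- iso_df[sel, ]
    if (all(d$pct == 0 | is.na(d$pct))) return(NULL)
    g <- .split_groups(d$pct, d$genotype, ref_group, alt_group)
    res <- gated_test(g$wt, g$ko)
    wt_mean <- mean(g$wt); ko_mean <- mean(g$ko)
    data.frame(region = combos$region[i], pattern = combos$pattern[i],
               wt_mean_pct = wt_mean, ko_mean_pct = ko_mean,
               ko_wt_ratio = if (wt_mean > 0) ko_mean / wt_mean else NA_real_,
               p = res$p, test = res$test,
               significant = res$p < alpha,
               low_abundance = wt_mean < low_abundance_pct,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " pattern(s) absent in all samples were omitted")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no isoform present in any sample")
  out[order(out$region, match(out$pattern, rownames(enumerate_patterns()))), ]
}

#' Multiple-testing adjustment of a differential table
#'
#' \code{method = "none"} reproduces the convention of reporting raw
#' p-values; \code{"bh"} adds a Benjamini-Hochberg adjusted p-value,
#' computed within each region.
#'
#' @param rows Differential table with a \code{p} column (and optionally
#'   \code{region}).
#' @param method \code{"none"} or \code{"bh"}.
#' @param alpha Level used to refresh the \code{significant} flag (against
#'   the adjusted p when \code{method = "bh"}).
#' @return The table with a \code{p_adj} column appended.
#' @export
multiple_testing <- function(rows, method = c("none", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  if (method == "none") {
    rows$p_adj <- rows$p
  } else if (is.null(rows$region)) {
    rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
  } else {
    rows$p_adj <- stats::ave(rows$p, rows$region,
                             FUN = function(p) stats::p.adjust(p, "BH"))
  }
  if (!is.null(rows$significant)) rows$significant <- rows$p_adj < alpha
  rows
}
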