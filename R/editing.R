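# Per-read editing calls, per-sample site frequencies, isoform tabulation.
#
# Calling rule: at each of the five sites, a read contributes an EDITED call
# for G and an UNEDITED call for A, in both cases only when the base quality
# is at least min_q (default Q20).  Low-quality bases, non-A/G bases
# (sequencing errors to C/T carry no editing information) and uncovered
# sites are MASKED.  Per-site frequencies use every covered read; the
# 32-class isoform table uses only reads with all five sites called, since a
# partial read cannot be assigned to one of the 32 classes without
# imputation.

.CALL_LEVELS <- c("edited", "unedited", "masked")

#' Call editing state at the five sites for each aligned read
#'
#' @param aligned Data.frame of aligned reads ([align_reads()] or
#'   [load_sam()] output), in reference orientation.
#' @param ref An \code{amplicon_ref}.
#' @param min_q Minimum Phred quality for a base to be called (default 20).
#' @return An object of class \code{site_calls}: list with \code{id},
#'   \code{calls} (character matrix, one row per read, columns in display
#'   order A, B, C, D, E with values \code{edited}/\code{unedited}/
#'   \code{masked}) and \code{complete} (logical; no masked entry).
#' @export
call_sites <- function(aligned, ref, min_q = 20) {
  n <- nrow(aligned)
  calls <- matrix("masked", nrow = n, ncol = 5,
                  dimnames = list(NULL, .SITES_DISPLAY))
  if (n > 0) {
    len <- nchar(aligned$seq)
    for (s in .SITES_DISPLAY) {
      idx <- ref$site_offsets[[s]] - aligned$start + 1L
      cov <- which(idx >= 1L & idx <= len)
      if (!length(cov)) next
      base <- substring(aligned$seq[cov], idx[cov], idx[cov])
      qc <- substring(aligned$qual[cov], idx[cov], idx[cov])
      q <- as.integer(charToRaw(paste0(qc, collapse = ""))) - 33L
      good <- q >= min_q
      calls[cov[good & base == "G"], s] <- "edited"
      calls[cov[good & base == "A"], s] <- "unedited"
    }
  }
  structure(list(id = aligned$id, calls = calls,
                 complete = rowSums(calls == "masked") == 0),
            class = "site_calls")
}

#' Per-site editing frequencies
#'
#' @param calls A \code{site_calls} object.
#' @return Data.frame with one row per site (display order): \code{site},
#'   \code{n_covered} (non-masked calls), \code{n_edited}, \code{pct}
#'   (100 * n_edited / n_covered; \code{NA} — reported missing, not 0% —
#'   when no read covers the site).
#' @export
site_frequencies <- function(calls) {
  stopifnot(inherits(calls, "site_calls"))
  if (nrow(calls$calls) == 0) stop("empty call collection")
  n_covered <- colSums(calls$calls != "masked")
  n_edited <- colSums(calls$calls == "edited")
  pct <- ifelse(n_covered > 0, 100 * n_edited / n_covered, NA_real_)
  data.frame(site = .SITES_DISPLAY, n_covered = as.integer(n_covered),
             n_edited = as.integer(n_edited), pct = pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate the 32 isoform classes
#'
#' Counts only reads with all five sites called; each such read increments
#' exactly one pattern bin.  Incomplete reads are counted separately and
#' reported via the \code{n_incomplete} attribute.
#'
#' @param calls A \code{site_calls} object.
#' @return Named integer 32-vector in the pattern order of
#'   [enumerate_patterns()], with attribute \code{n_incomplete}.
#' @export
isoform_counts <- function(calls) {
  stopifnot(inherits(calls, "site_calls"))
  cm <- calls$calls[calls$complete, , drop = FALSE]
  bits <- (cm == "edited") + 0L
  idx <- as.integer(bits %*% c(16L, 8L, 4L, 2L, 1L)) + 1L
  counts <- stats::setNames(tabulate(idx, 32L), rownames(enumerate_patterns()))
  attr(counts, "n_incomplete") <- sum(!calls$complete)
  counts
}

#' Profile one sample: site frequencies, isoforms, recoding
#'
#' Composes [call_sites()], [site_frequencies()] and [isoform_counts()] for
#' one sample's aligned reads.  The site table uses all covered reads; a
#' complete-reads-only site table (the exact marginal of the isoform
#' 32-vector) is also provided.
#'
#' @param aligned Data.frame of aligned reads.
#' @param ref An \code{amplicon_ref}.
#' @param metadata List with \code{sample}, and optionally \code{genotype},
#'   \code{region}, \code{mouse}.
#' @param min_q Minimum base quality for a call (default 20).
#' @return Object of class \code{sample_editing_profile}: metadata fields,
#'   \code{sites} and \code{sites_complete} data.frames, \code{isoforms}
#'   data.frame (\code{pattern}, \code{count}, \code{pct} of complete reads,
#'   \code{tripeptide}), \code{n_reads}, \code{n_complete},
#'   \code{n_incomplete}.
#' @export
profile_sample <- function(aligned, ref, metadata = list(sample = "sample"),
                           min_q = 20) {
  if (is.null(metadata$sample)) metadata$sample <- "sample"
  if (nrow(aligned) == 0)
    stop("no accepted reads for sample '", metadata$sample, "'")
  calls <- call_sites(aligned, ref, min_q = min_q)
  sites <- site_frequencies(calls)
  counts <- isoform_counts(calls)
  n_complete <- sum(calls$complete)
  rec <- recoding_table(ref)

  complete_calls <- structure(
    list(id = calls$id[calls$complete],
         calls = calls$calls[calls$complete, , drop = FALSE],
         complete = rep(TRUE, n_complete)), class = "site_calls")
  sites_complete <- if (n_complete > 0) site_frequencies(complete_calls)
                    else sites[0, ]

  isoforms <- data.frame(
    pattern = names(counts),
    count = as.integer(counts),
    pct = if (n_complete > 0) 100 * as.integer(counts) / n_complete
          else NA_real_,
    tripeptide = rec$tripeptide[match(names(counts), rec$pattern)],
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    sample = metadata$sample,
    genotype = metadata$genotype %||% NA_character_,
    region = metadata$region %||% NA_character_,
    sites = sites,
    sites_complete = sites_complete,
    isoforms = isoforms,
    n_reads = nrow(aligned),
    n_complete = n_complete,
    n_incomplete = attr(counts, "n_incomplete")
  ), class = "sample_editing_profile")
}

#' @export
print.sample_editing_profile <- function(x, ...) {
  cat("Editing profile for sample '", x$sample, "'",
      if (!is.na(x$genotype)) paste0(" (", x$genotype,
                                     if (!is.na(x$region))
                                       paste0(", ", x$region), ")"),
      "\n", sep = "")
  cat("  reads:", x$n_reads, "aligned;", x$n_complete, "complete,",
      x$n_incomplete, "incomplete\n")
  sfmt <- sprintf("%s=%.2f%%", x$sites$site, x$sites$pct)
  cat("  site editing:", paste(sfmt, collapse = "  "), "\n")
  top <- x$isoforms[order(-x$isoforms$count), ][1:3, ]
  cat("  top isoforms:",
      paste(sprintf("%s (%s) %.2f%%", top$pattern, top$tripeptide, top$pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a sample profile as TSV
#'
#' Emits \code{<sample>_sites.tsv} (site, n_covered, n_edited, pct) and
#' \code{<sample>_isoforms.tsv} (pattern, count, pct, tripeptide), with
#' percentages rounded to 2 decimals and rows in deterministic order.
#'
#' @param profile A \code{sample_editing_profile}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_profile <- function(profile, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sites <- profile$sites
  sites$pct <- round(sites$pct, 2)
  iso <- profile$isoforms
  iso$pct <- round(iso$pct, 2)
  p1 <- file.path(dir, paste0(profile$sample, "_sites.tsv"))
  p2 <- file.path(dir, paste0(profile$sample, "_isoforms.tsv"))
  utils::write.table(sites, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(iso, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Long-format site table across samples
#'
#' @param profiles List of \code{sample_editing_profile} objects.
#' @param complete_only Use the complete-reads-only site frequencies
#'   instead of the all-covered default.
#' @return Data.frame: \code{sample}, \code{genotype}, \code{region},
#'   \code{site}, \code{n_covered}, \code{n_edited}, \code{pct}.
#' @export
site_table <- function(profiles, complete_only = FALSE) {
  do.call(rbind, lapply(profiles, function(p) {
    s <- if (complete_only) p$sites_complete else p$sites
    cbind(data.frame(sample = p$sample, genotype = p$genotype,
                     region = p$region, stringsAsFactors = FALSE),
          s, row.names = NULL)
  }))
}

#' Long-format isoform table across samples
#'
#' @param profiles List of \code{sample_editing_profile} objects.
#' @return Data.frame: \code{sample}, \code{genotype}, \code{region},
#'   \code{pattern}, \code{count}, \code{pct}, \code{tripeptide}.
#' @export
isoform_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cbind(data.frame(sample = p$sample, genotype = p$genotype,
                     region = p$region, stringsAsFactors = FALSE),
          p$isoforms, row.names = NULL)
  }))
}
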