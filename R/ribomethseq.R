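# RiboMeth-seq 2'-O-methylation scoring from 5'-end count profiles.
#
# Alkaline fragmentation cleaves every phosphodiester bond at a similar
# rate except the bond 3' of a 2'-O-methylated ribose, which is protected.
# A methyl at nucleotide m therefore depletes sequencing-read 5' ends at
# position m + 1; the score converts that local deficit, relative to a
# weighted neighbourhood average, into a methylation level in [0, 1].

#' Cleavage-coordinate offset
#'
#' A 2'-O-methyl at nucleotide m suppresses read 5' ends at position
#' m + \code{RMS_CLEAVAGE_OFFSET}.  The generator and the scorer share this
#' single constant.
#' @export
RMS_CLEAVAGE_OFFSET <- 1L

#' Scored (cleavage) position of a methylated nucleotide
#'
#' @param site Methylated nucleotide position(s), 1-based.
#' @return The position(s) whose 5'-end count the methyl suppresses.
#' @export
scored_position <- function(site) site + RMS_CLEAVAGE_OFFSET

#' Methylation score at one position
#'
#' Score-C-style drop statistic: \eqn{\max(0, 1 - n_{pos}/w)} where
#' \eqn{w} is the weighted mean of the end counts at offsets \eqn{\pm 1}
#' to \eqn{\pm k}, with linearly decreasing weights \eqn{k, k-1, \ldots, 1}.
#' Scored positions of other annotated sites are excluded from the
#' neighbourhood so adjacent methylations do not depress the baseline.
#'
#' @param profile An \code{end_count_profile} (or a bare count vector).
#' @param pos Position to score, in cleavage coordinates (use
#'   [scored_position()] to convert a methylated nucleotide position).
#' @param k Half-window width in positions (default 6).
#' @return Score in \[0, 1\], or \code{NA} when the neighbourhood mean is 0
#'   (undefined).
#' @export
meth_score <- function(profile, pos, k = 6) {
  counts <- if (inherits(profile, "end_count_profile")) profile$counts
            else profile
  n <- length(counts)
  if (pos < 1 || pos > n) stop("position ", pos, " out of range [1, ", n, "]")
  if (pos - 1 < 1 || pos + 1 > n)
    stop("position ", pos, " needs at least one in-range neighbour on each side")
  excl <- if (inherits(profile, "end_count_profile"))
    setdiff(profile$sites$scored_pos, pos) else integer(0)
  offs <- c(-(1:k), 1:k)
  wts <- c(k:1, k:1)
  nb <- pos + offs
  keep <- nb >= 1 & nb <= n & !(nb %in% excl)
  w <- sum(wts[keep] * counts[nb[keep]]) / sum(wts[keep])
  if (w == 0) return(NA_real_)
  max(0, 1 - counts[pos] / w)
}

#' Methylation scores at several positions
#'
#' @param profile An \code{end_count_profile} or count vector.
#' @param positions Cleavage positions to score; defaults to the profile's
#'   annotated sites.
#' @param k Half-window width.
#' @return Named numeric vector of scores.
#' @export
meth_scores <- function(profile, positions = NULL, k = 6) {
  if (is.null(positions)) {
    if (!inherits(profile, "end_count_profile") ||
        nrow(profile$sites) == 0)
      stop("positions must be given when the profile carries no annotation")
    positions <- stats::setNames(profile$sites$scored_pos,
                                 profile$sites$name)
  }
  vapply(positions, function(p) meth_score(profile, p, k = k), numeric(1))
}

#' Compare methylation scores between genotype groups
#'
#' Per annotated site, the replicate scores of the two groups are compared
#' with the same normality-gated test used for differential editing.
#' Significance tiers follow the usual asterisk convention
#' (0.05 / 0.01 / 0.001).
#'
#' @param wt_profiles,ko_profiles Lists of \code{end_count_profile}
#'   replicates (the annotation of the first WT profile defines the site
#'   set unless \code{sites} is given).
#' @param sites Optional data.frame with \code{position} (methylated
#'   nucleotide, 1-based) and \code{name}.
#' @param k Half-window width for the score.
#' @return Data.frame: \code{position}, \code{name}, \code{mean_wt},
#'   \code{mean_ko}, \code{p}, \code{test}, \code{stars}.
#' @export
compare_meth <- function(wt_profiles, ko_profiles, sites = NULL, k = 6) {
  stopifnot(length(wt_profiles) >= 2, length(ko_profiles) >= 2)
  if (is.null(sites)) sites <- wt_profiles[[1]]$sites[, c("position", "name")]
  scored <- scored_position(sites$position)
  group_scores <- function(profiles) {
    vapply(profiles, function(pr)
      vapply(scored, function(p) meth_score(pr, p, k = k), numeric(1)),
      numeric(length(scored)))
  }
  sw <- matrix(group_scores(wt_profiles), nrow = length(scored))
  sk <- matrix(group_scores(ko_profiles), nrow = length(scored))
  rows <- lapply(seq_along(scored), function(i) {
    x <- sw[i, ]; y <- sk[i, ]
    if (anyNA(x) || anyNA(y)) {
      warning("site ", sites$name[i],
              ": replicate(s) with undefined score excluded")
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
    }
    res <- gated_test(x, y)
    data.frame(position = sites$position[i], name = sites$name[i],
               mean_wt = mean(x), mean_ko = mean(y),
               p = res$p, test = res$test,
               stars = as.character(cut(res$p, c(0, 0.001, 0.01, 0.05, 1),
                                        labels = c("***", "**", "*", ""),
                                        include.lowest = TRUE)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
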