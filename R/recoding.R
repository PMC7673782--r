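# Combinatorics of the five editing sites and protein recoding.
#
# The editing state of a read is a binary pattern over sites A-E; 2^5 = 32
# patterns define the mRNA isoform classes.  Editing recodes residues 156,
# 158 and 160 of the receptor's second intracellular loop; translating all
# patterns yields 24 distinct tripeptides because several codon edits are
# synonymous at the protein level (e.g. A alone and A+B both give Val-156).

#' Enumerate all editing patterns
#'
#' Returns the 32 binary editing patterns over the five sites as a 0/1
#' matrix with columns in display order A, B, C, D, E.  Rows are sorted in
#' binary order with site A as the most significant bit, so the first row is
#' the unedited pattern and the last is the fully edited one.
#'
#' @return A 32 x 5 integer matrix with rownames giving the pattern label
#'   (concatenated edited-site letters; \code{"none"} for the unedited
#'   pattern).
#' @export
enumerate_patterns <- function() {
  grid <- expand.grid(E = 0:1, D = 0:1, C = 0:1, B = 0:1, A = 0:1)
  m <- as.matrix(grid[, .SITES_DISPLAY])
  rownames(m) <- pattern_label(m)
  m
}

#' Label an editing pattern
#'
#' @param bits A 0/1 vector named by site (any order covering A-E), or a
#'   matrix with sites as columns.
#' @return Character label(s): edited-site letters concatenated in display
#'   order, \code{"none"} if unedited.
#' @export
pattern_label <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1,
                                         dimnames = list(NULL, names(bits)))
  bits <- bits[, .SITES_DISPLAY, drop = FALSE]
  apply(bits, 1, function(b) {
    lab <- paste0(.SITES_DISPLAY[b == 1], collapse = "")
    if (lab == "") "none" else lab
  })
}

# Translate one pattern by editing the reference codons and applying the
# standard genetic code.  A->I editing is read as A->G by the ribosome.
.translate_bits <- function(bits, ref) {
  vapply(ref$codon_map, function(cm) {
    codon <- strsplit(cm$codon, "")[[1]]
    for (s in cm$sites) {
      if (bits[[s]] == 1) {
        pos_in_codon <- ref$site_offsets[[s]] - cm$start + 1L
        codon[pos_in_codon] <- "G"
      }
    }
    unname(Biostrings::GENETIC_CODE[[paste0(codon, collapse = "")]])
  }, character(1))
}

#' Build the recoding table
#'
#' Maps each of the 32 editing patterns to the tripeptide it encodes at
#' residues 156, 158 and 160.  The map is derived at run time by editing the
#' reference codons and translating with the standard genetic code, so an
#' injected alternative codon table flows through automatically.
#'
#' @param ref An \code{amplicon_ref} (default reference if omitted).
#' @return A data.frame with one row per pattern: \code{pattern} (label),
#'   columns \code{A}..\code{E} (0/1), \code{aa156}, \code{aa158},
#'   \code{aa160} and \code{tripeptide} (e.g. \code{"INI"}, \code{"VGV"}).
#' @examples
#' tab <- recoding_table()
#' length(unique(tab$tripeptide))  # 24 protein isoforms from 32 mRNAs
#' @export
recoding_table <- function(ref = amplicon_reference()) {
  pats <- enumerate_patterns()
  aas <- t(apply(pats, 1, .translate_bits, ref = ref))
  colnames(aas) <- c("aa156", "aa158", "aa160")
  data.frame(
    pattern = rownames(pats),
    pats,
    aas,
    tripeptide = paste0(aas[, 1], aas[, 2], aas[, 3]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Translate a single editing pattern
#'
#' @param bits Named 0/1 vector over sites A-E (any order), or a pattern
#'   label such as \code{"ABD"} or \code{"none"}.
#' @param table A recoding table from [recoding_table()]; rebuilt from the
#'   default reference if omitted.
#' @return The tripeptide string, e.g. \code{"VGV"} for the fully edited
#'   pattern.
#' @export
translate_pattern <- function(bits, table = recoding_table()) {
  if (is.character(bits) && length(bits) == 1) {
    lab <- bits
  } else {
    lab <- pattern_label(bits)
  }
  hit <- match(lab, table$pattern)
  if (anyNA(hit)) stop("unknown editing pattern: ", lab[is.na(hit)][1])
  table$tripeptide[hit]
}
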