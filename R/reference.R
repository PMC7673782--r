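# Amplicon reference for the Htr2c editing locus.
#
# Coordinate conventions: all offsets in this module are 0-based, and
# intervals are half-open.  The five editable adenosines occur in genomic
# (5'->3') order A, B, E, C, D; outputs elsewhere relabel columns in the
# conventional naming order A, B, C, D, E.

#' Editing-site order along the amplicon (genomic 5'->3')
#' @keywords internal
.SITES_GENOMIC <- c("A", "B", "E", "C", "D")

#' Editing-site order used for display and tabulation
#' @keywords internal
.SITES_DISPLAY <- c("A", "B", "C", "D", "E")

# Deterministic, non-repetitive filler around the recoded codons.  A small
# fixed linear congruential generator keeps the reference independent of R's
# global RNG state; the pipeline never depends on filler identity.
.filler_sequence <- function(n, state = 987654321) {
  out <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    state <- (1103515245 * (state %% 2^16) + 12345) %% 2147483648
    out[i] <- bases[(state %/% 65536) %% 4 + 1]
  }
  paste0(out, collapse = "")
}

#' Build the Htr2c amplicon reference
#'
#' Constructs the 249-nt amplicon spanning the spliced exon IV/V junction of
#' \emph{Htr2c}, with the three recoded codons of the second intracellular
#' loop embedded in frame: residue 156 (ATA, Ile; editing sites A and B at
#' codon positions 1 and 3), residue 158 (AAT, Asn; sites E and C at codon
#' positions 1 and 2) and residue 160 (ATT, Ile; site D at codon position 1).
#' The five sites therefore fall in genomic order A, B, E, C, D.  Filler
#' sequence around the codons is a fixed arbitrary non-repetitive string;
#' none of the downstream computations depend on it.
#'
#' @param length Total amplicon length in nucleotides (default 249).
#' @param junction_offset 0-based position of the exon IV/V junction.
#' @param codon156_offset 0-based start of the codon for residue 156.
#'   Codons 158 and 160 follow in frame (offsets +6 and +12).
#' @param name Sequence identifier used in FASTA/SAM output.
#' @return An object of class \code{amplicon_ref}: a list with fields
#'   \code{name}, \code{sequence}, \code{site_offsets} (named 0-based
#'   positions in genomic order A, B, E, C, D), \code{codon_map} (residue
#'   index -> codon start offset and reference codon) and
#'   \code{junction_offset}.
#' @examples
#' ref <- amplicon_reference()
#' nchar(ref$sequence)      # 249
#' ref$site_offsets
#' @export
amplicon_reference <- function(length = 249, junction_offset = 100,
                               codon156_offset = 120, name = "Htr2c_amplicon") {
  span_end <- codon156_offset + 15 # end of codon 160 (offsets +12..+14)
  if (length < span_end)
    stop("configuration error: amplicon length ", length,
         " is shorter than the span of the recoded codons (needs >= ",
         span_end, ")")
  if (junction_offset < 0 || junction_offset >= length)
    stop("configuration error: junction_offset outside the amplicon")
  if (codon156_offset <= junction_offset)
    stop("configuration error: recoded codons must lie 3' of the junction (exon V)")

  seq_chars <- strsplit(.filler_sequence(length), "")[[1]]
  codons <- c(`156` = "ATA", `158` = "AAT", `160` = "ATT")
  starts <- c(`156` = codon156_offset, `158` = codon156_offset + 6L,
              `160` = codon156_offset + 12L)
  for (res in names(codons)) {
    s <- starts[[res]]
    seq_chars[(s + 1):(s + 3)] <- strsplit(codons[[res]], "")[[1]]
  }

  site_offsets <- c(
    A = starts[["156"]],      # codon 156, position 1
    B = starts[["156"]] + 2L, # codon 156, position 3
    E = starts[["158"]],      # codon 158, position 1
    C = starts[["158"]] + 1L, # codon 158, position 2
    D = starts[["160"]]       # codon 160, position 1
  )

  ref <- structure(list(
    name = name,
    sequence = paste0(seq_chars, collapse = ""),
    site_offsets = site_offsets,
    codon_map = list(
      `156` = list(start = starts[["156"]], codon = codons[["156"]],
                   sites = c("A", "B")),
      `158` = list(start = starts[["158"]], codon = codons[["158"]],
                   sites = c("E", "C")),
      `160` = list(start = starts[["160"]], codon = codons[["160"]],
                   sites = "D")
    ),
    junction_offset = as.integer(junction_offset)
  ), class = "amplicon_ref")
  .validate_amplicon_ref(ref)
  ref
}

.validate_amplicon_ref <- function(ref) {
  off <- ref$site_offsets
  L <- nchar(ref$sequence)
  stopifnot(
    identical(names(off), .SITES_GENOMIC),
    all(diff(off) > 0), all(off >= 0), all(off < L)
  )
  bases <- substring(ref$sequence, off + 1, off + 1)
  if (!all(bases == "A"))
    stop("invalid reference: editing-site positions must carry 'A'")
  aas <- vapply(ref$codon_map, function(cm) {
    unname(Biostrings::GENETIC_CODE[[substr(ref$sequence, cm$start + 1,
                                            cm$start + 3)]])
  }, character(1))
  if (!identical(unname(aas), c("I", "N", "I")))
    stop("invalid reference: codons 156/158/160 must encode Ile, Asn, Ile")
  invisible(ref)
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat("Htr2c amplicon reference '", x$name, "' (", nchar(x$sequence),
      " nt)\n", sep = "")
  cat("  exon IV/V junction at 0-based offset", x$junction_offset, "\n")
  cat("  editing sites (genomic order):",
      paste(sprintf("%s=%d", names(x$site_offsets), x$site_offsets),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write the amplicon reference as FASTA
#'
#' @param ref An \code{amplicon_ref}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}
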