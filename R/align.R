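# Anchored gapless alignment of amplicon reads, plus SAM interchange.
#
# Amplicon reads rarely need gapped alignment, so the internal aligner
# scans every gapless placement of a read (and its reverse complement)
# against the reference and keeps the best.  Editing-site columns are
# excluded from the mismatch count so that heavily edited reads are not
# penalized.  Reads may alternatively enter from a SAM/BAM produced by an
# external genome aligner restricted to the amplicon locus.

.COMP_RAW <- local({
  tbl <- as.raw(0:255)
  from <- charToRaw("ACGTacgt")
  to <- charToRaw("TGCAtgca")
  tbl[as.integer(from) + 1L] <- to
  tbl
})

.revcomp_raw <- function(m) {
  rc <- .COMP_RAW[as.integer(m) + 1L]
  dim(rc) <- dim(m)
  rc[rev(seq_len(nrow(rc))), , drop = FALSE]
}

.reverse_string <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# raw L x n matrix from equal-length strings
.string_matrix <- function(x, len) {
  matrix(charToRaw(paste0(x, collapse = "")), nrow = len)
}

#' Align reads to the amplicon reference
#'
#' Gapless alignment at the best-scoring offset over all placements of each
#' read and of its reverse complement.  A read is accepted iff its mismatch
#' count (editing-site columns excluded) is at most
#' \code{max_mismatch_frac * read length}.  Reverse-strand reads are
#' re-oriented to the reference strand, with qualities reversed and the
#' strand recorded.
#'
#' @param reads Character vector of read sequences (or a
#'   \code{simulated_reads} object, in which case \code{quals}/\code{ids}
#'   are taken from it).
#' @param quals Phred+33 quality strings, same lengths as \code{reads}.
#' @param ids Read identifiers; defaults to \code{read_<i>}.
#' @param ref An \code{amplicon_ref}.
#' @param max_mismatch_frac Acceptance threshold on the mismatch fraction
#'   (default 0.1).
#' @return A list with \code{aligned} (data.frame: \code{id}, \code{start}
#'   0-based, \code{strand}, \code{seq} and \code{qual} in reference
#'   orientation, \code{n_mismatch}, \code{source}) and \code{rejected}
#'   (data.frame: \code{id}, \code{reason} in
#'   \{\code{longer_than_reference}, \code{max_mismatch}\}).
#' @export
align_reads <- function(reads, quals = NULL, ids = NULL, ref,
                        max_mismatch_frac = 0.1) {
  if (inherits(reads, "simulated_reads")) {
    quals <- reads$qual; ids <- reads$id; reads <- reads$seq
  }
  n <- length(reads)
  if (n == 0) stop("no reads supplied")
  if (is.null(quals)) quals <- vapply(nchar(reads), function(k)
    strrep("I", k), character(1))
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  stopifnot(length(quals) == n, all(nchar(quals) == nchar(reads)))

  refraw <- charToRaw(ref$sequence)
  L <- length(refraw)
  site1 <- ref$site_offsets + 1L

  start <- integer(n); strand <- character(n); nm <- integer(n)
  oriented_seq <- character(n); oriented_qual <- character(n)
  reason <- character(n)
  ok <- logical(n)

  for (len in unique(nchar(reads))) {
    sel <- which(nchar(reads) == len)
    if (len > L) { reason[sel] <- "longer_than_reference"; next }
    m <- .string_matrix(reads[sel], len)
    rc <- .revcomp_raw(m)
    k <- length(sel)
    best_mm <- rep(Inf, k); best_off <- integer(k); best_rev <- logical(k)
    for (off in 0:(L - len)) {
      win <- refraw[(off + 1):(off + len)]
      sr <- site1 - off
      keep <- setdiff(seq_len(len), sr[sr >= 1 & sr <= len])
      mmf <- colSums(m[keep, , drop = FALSE] != win[keep])
      upd <- mmf < best_mm
      best_mm[upd] <- mmf[upd]; best_off[upd] <- off; best_rev[upd] <- FALSE
      mmr <- colSums(rc[keep, , drop = FALSE] != win[keep])
      upd <- mmr < best_mm
      best_mm[upd] <- mmr[upd]; best_off[upd] <- off; best_rev[upd] <- TRUE
    }
    acc <- best_mm <= max_mismatch_frac * len
    ok[sel] <- acc
    reason[sel[!acc]] <- "max_mismatch"
    start[sel] <- best_off
    strand[sel] <- ifelse(best_rev, "-", "+")
    nm[sel] <- as.integer(best_mm)
    oriented_seq[sel] <- reads[sel]
    oriented_qual[sel] <- quals[sel]
    if (any(best_rev)) {
      rev_idx <- sel[best_rev]
      rc_str <- apply(rc[, best_rev, drop = FALSE], 2, rawToChar)
      oriented_seq[rev_idx] <- rc_str
      oriented_qual[rev_idx] <- .reverse_string(quals[rev_idx])
    }
  }

  list(
    aligned = data.frame(
      id = ids[ok], start = start[ok], strand = strand[ok],
      seq = oriented_seq[ok], qual = oriented_qual[ok],
      n_mismatch = nm[ok], source = rep("internal", sum(ok)),
      stringsAsFactors = FALSE),
    rejected = data.frame(id = ids[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE)
  )
}

#' Merge overlapping paired-end mates
#'
#' Both mates must already be in reference orientation with 0-based start
#' offsets.  At overlapping positions the base from the mate with the higher
#' quality wins; if the mates disagree and both qualities are at or above
#' \code{disagree_q}, the position is masked (base \code{N}, quality 2), so
#' it is excluded from downstream editing calls.
#'
#' @param seq1,qual1,start1 First mate (sequence, Phred+33 quality, start).
#' @param seq2,qual2,start2 Second mate.
#' @param disagree_q Quality threshold above which a disagreement masks the
#'   position (default 20).
#' @return List with merged \code{seq}, \code{qual} and \code{start}.
#' @export
merge_mates <- function(seq1, qual1, start1, seq2, qual2, start2,
                        disagree_q = 20) {
  if (start1 > start2) {
    tmp <- list(seq1, qual1, start1)
    seq1 <- seq2; qual1 <- qual2; start1 <- start2
    seq2 <- tmp[[1]]; qual2 <- tmp[[2]]; start2 <- tmp[[3]]
  }
  end1 <- start1 + nchar(seq1)
  if (start2 > end1)
    stop("mates do not overlap or abut; cannot merge (gap of ",
         start2 - end1, " bases)")
  end2 <- start2 + nchar(seq2)
  span <- max(end1, end2) - start1
  s <- raw(span); q <- integer(span)
  i1 <- seq_len(nchar(seq1))
  s[i1] <- charToRaw(seq1)
  q[i1] <- as.integer(charToRaw(qual1)) - 33L
  i2 <- (start2 - start1) + seq_len(nchar(seq2))
  s2 <- charToRaw(seq2)
  q2 <- as.integer(charToRaw(qual2)) - 33L
  ov <- i2 <= nchar(seq1)
  # non-overlapping tail of mate 2
  s[i2[!ov]] <- s2[!ov]
  q[i2[!ov]] <- q2[!ov]
  if (any(ov)) {
    io <- i2[ov]
    agree <- s[io] == s2[ov]
    clash <- !agree & q[io] >= disagree_q & q2[ov] >= disagree_q
    take2 <- !agree & !clash & (q2[ov] > q[io])
    s[io[take2]] <- s2[ov][take2]
    q[io[take2]] <- q2[ov][take2]
    better <- agree & (q2[ov] > q[io])
    q[io[better]] <- q2[ov][better]
    s[io[clash]] <- charToRaw("N")
    q[io[clash]] <- 2L
  }
  list(seq = rawToChar(s),
       qual = rawToChar(as.raw(q + 33L)),
       start = start1)
}

#' Write aligned reads as SAM
#'
#' Minimal SAM 1.6 emitter for internally aligned reads: one \code{@SQ}
#' line for the amplicon, gapless CIGAR, flag 16 for reverse-strand reads
#' (sequence is stored in reference orientation, as SAM requires).
#'
#' @param aligned Data.frame from [align_reads()]\code{$aligned}.
#' @param ref An \code{amplicon_ref}.
#' @param path Output SAM path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(aligned, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, nchar(ref$sequence)))
  flag <- ifelse(aligned$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                 aligned$id, flag, ref$name, aligned$start + 1L,
                 nchar(aligned$seq), aligned$seq, aligned$qual)
  writeLines(c(header, rec), path)
  invisible(path)
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("region must be 'chrom:start-end' (1-based, inclusive)")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Load alignments from SAM/BAM and convert to amplicon coordinates
#'
#' Yields primary, mapped alignments; secondary and supplementary records
#' are skipped, as are records whose CIGAR contains indels or skips
#' (soft-clipped ends are trimmed).  Reads extending past the amplicon are
#' truncated to it.  Mismatch counts are recomputed against the amplicon
#' with editing-site columns excluded, mirroring the internal aligner.
#'
#' @param path SAM or BAM file.
#' @param ref An \code{amplicon_ref}.
#' @param region Optional \code{"chrom:start-end"} (1-based, inclusive)
#'   giving the amplicon locus on the coordinate system the file was mapped
#'   to.  When \code{NULL}, records must be mapped directly to
#'   \code{ref$name}.
#' @return Data.frame in the [align_reads()] \code{aligned} layout with
#'   \code{source = "sam"}; attributes \code{n_retained} and
#'   \code{n_skipped} carry the filtering counts (also reported via
#'   \code{message}).
#' @export
load_sam <- function(path, ref, region = NULL) {
  bam <- tryCatch({
    if (grepl("\\.bam$", path, ignore.case = TRUE)) path
    else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  }, error = function(e)
    stop("SAM parse error in '", path, "': ", conditionMessage(e)))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")))[[1]]
  n_total <- length(res$qname)
  if (n_total == 0) stop("no records in '", path, "'")

  flag <- res$flag
  keep <- !is.na(res$pos) &
    bitwAnd(flag, 0x4) == 0 &    # mapped
    bitwAnd(flag, 0x100) == 0 &  # not secondary
    bitwAnd(flag, 0x800) == 0    # not supplementary

  if (is.null(region)) {
    keep <- keep & as.character(res$rname) == ref$name
    origin <- 1L
  } else {
    reg <- .parse_region(region)
    keep <- keep & as.character(res$rname) == reg$chrom &
      res$pos <= reg$end
    origin <- reg$start
  }

  L <- nchar(ref$sequence)
  out <- vector("list", sum(keep))
  j <- 0L; n_cigar_skip <- 0L
  for (i in which(keep)) {
    parsed <- .apply_cigar(res$cigar[i], as.character(res$seq[i]),
                           as.character(res$qual[i]))
    if (is.null(parsed)) { n_cigar_skip <- n_cigar_skip + 1L; next }
    start0 <- res$pos[i] - origin
    sq <- parsed$seq; ql <- parsed$qual
    if (start0 < 0) { # truncate bases upstream of the amplicon
      cut <- -start0
      if (cut >= nchar(sq)) { n_cigar_skip <- n_cigar_skip + 1L; next }
      sq <- substring(sq, cut + 1); ql <- substring(ql, cut + 1)
      start0 <- 0L
    }
    if (start0 + nchar(sq) > L) {
      keep_len <- L - start0
      if (keep_len <= 0) { n_cigar_skip <- n_cigar_skip + 1L; next }
      sq <- substring(sq, 1, keep_len); ql <- substring(ql, 1, keep_len)
    }
    j <- j + 1L
    out[[j]] <- list(id = res$qname[i], start = as.integer(start0),
                     strand = if (bitwAnd(flag[i], 0x10)) "-" else "+",
                     seq = sq, qual = ql)
  }
  if (j == 0) stop("no usable alignments on the amplicon in '", path, "'")
  out <- out[seq_len(j)]
  df <- data.frame(
    id = vapply(out, `[[`, character(1), "id"),
    start = vapply(out, `[[`, integer(1), "start"),
    strand = vapply(out, `[[`, character(1), "strand"),
    seq = vapply(out, `[[`, character(1), "seq"),
    qual = vapply(out, `[[`, character(1), "qual"),
    source = "sam", stringsAsFactors = FALSE)
  df$n_mismatch <- .count_mismatches(df, ref)
  df <- df[, c("id", "start", "strand", "seq", "qual", "n_mismatch", "source")]
  n_skipped <- n_total - j
  message(sprintf("load_sam: retained %d of %d records (%d filtered, %d unusable CIGAR/region)",
                  j, n_total, n_total - sum(keep), n_cigar_skip))
  attr(df, "n_retained") <- j
  attr(df, "n_skipped") <- n_skipped
  df
}

# Trim soft clips; reject CIGARs with indels/skips.  Returns NULL if the
# record cannot be represented as a gapless alignment.
.apply_cigar <- function(cigar, seq, qual) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0) return(NULL)
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  codes <- sub("^[0-9]+", "", ops)
  if (any(codes %in% c("I", "D", "N", "P"))) return(NULL)
  codes[codes %in% c("=", "X")] <- "M"
  aligned <- codes == "M"
  if (!any(aligned)) return(NULL)
  # hard clips consume nothing; soft clips are trimmed off seq/qual
  lead <- 0L
  for (k in seq_along(codes)) {
    if (codes[k] == "M") break
    if (codes[k] == "S") lead <- lead + lens[k]
  }
  m_len <- sum(lens[aligned])
  list(seq = substr(seq, lead + 1L, lead + m_len),
       qual = substr(qual, lead + 1L, lead + m_len))
}

.count_mismatches <- function(aligned, ref) {
  refraw <- charToRaw(ref$sequence)
  site1 <- ref$site_offsets + 1L
  vapply(seq_len(nrow(aligned)), function(i) {
    s <- charToRaw(aligned$seq[i])
    pos <- aligned$start[i] + seq_along(s)
    keep <- !(pos %in% site1)
    sum(s[keep] != refraw[pos[keep]])
  }, integer(1))
}
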