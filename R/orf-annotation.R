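# ORF discovery on spliced mRNA, main-CDS selection, and UTR derivation.
#
# Only the three forward frames of the mRNA are scanned: an mRNA is
# single-stranded, so reverse-strand ORFs do not exist at this level.
# Codons containing N never count as start or stop codons.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find complete ORFs on an mRNA sequence
#'
#' A complete ORF runs from an ATG to the first in-frame stop codon
#' (inclusive of the stop). Spans lacking a stop codon (incomplete ORFs)
#' are never reported. By default one ORF is reported per (frame, stop)
#' pair, anchored at the 5'-most ATG; `all_starts = TRUE` additionally
#' reports every nested ATG sharing that stop.
#'
#' @param seq mRNA sequence (A/C/G/T/N; case-insensitive).
#' @param min_len Minimum ORF length in nt, stop codon included. The
#'   default 3 mirrors the `-minsize 3` convention of EMBOSS getorf; a
#'   complete ORF is in practice always >= 6 nt.
#' @param all_starts Report nested ATGs (one row per start) instead of
#'   only the 5'-most start per stop.
#' @return `data.frame` with columns `start` (0-based position of the A of
#'   ATG), `end` (one past the last base of the stop codon), `length`
#'   (`end - start`), `frame` (`start %% 3`), sorted by `start`.
#' @export
find_complete_orfs <- function(seq, min_len = 3L, all_starts = FALSE) {
  stopifnot(min_len >= 3L)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), frame = integer(0))
  if (n < 6L) return(empty)
  res <- vector("list", 3L)
  for (frame in 0:2) {
    first <- frame + 1L
    if (first + 2L > n) next
    cpos <- seq.int(first, n - 2L, by = 3L)  # 1-based codon start positions
    codons <- substring(seq, cpos, cpos + 2L)
    A <- cpos[codons == "ATG"]
    S <- cpos[codons %in% STOP_CODONS]
    if (!length(A) || !length(S)) next
    # index of the stop that closes each start: first stop at position > A
    close_idx <- findInterval(A, S) + 1L
    ok <- close_idx <= length(S)
    A <- A[ok]; close_idx <- close_idx[ok]
    if (!length(A)) next
    if (!all_starts) {
      keep <- !duplicated(close_idx)  # A ascending => 5'-most start per stop
      A <- A[keep]; close_idx <- close_idx[keep]
    }
    end1 <- S[close_idx] + 2L  # 1-based inclusive end of stop codon
    res[[frame + 1L]] <- data.frame(start = A - 1L, end = end1,
                                    length = end1 - A + 1L, frame = frame)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[out$length >= max(min_len, 6L), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the main CDS among complete ORFs
#'
#' The CDS is the longest complete ORF; ties are broken toward the
#' 5'-most start. This is a documented stand-in for model-based CDS
#' callers: on synthetic data the planted CDS is guaranteed uniquely
#' longest, so the rule is exact there.
#'
#' @param orfs Output of [find_complete_orfs()] on one mRNA.
#' @param mrna_length Length of that mRNA in nt.
#' @param transcript_id Optional id carried through.
#' @return A `cds_annotation` list (`cds`, `utr5`, `utr3` intervals as
#'   `c(start, end)` half-open) or `NULL` when no complete ORF exists.
#' @export
select_cds <- function(orfs, mrna_length, transcript_id = NA_character_) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  o <- orfs[order(-orfs$length, orfs$start), , drop = FALSE]
  cds <- o[1L, ]
  if (cds$end > mrna_length) stop("CDS extends past mRNA end")
  utr <- extract_utrs(cds, mrna_length)
  structure(
    list(transcript_id = transcript_id, cds = cds,
         utr5 = utr$utr5, utr3 = utr$utr3, mrna_length = mrna_length),
    class = "cds_annotation"
  )
}

#' Derive UTR intervals from a CDS
#'
#' @param cds One-row ORF record (`start`, `end`) in mRNA coordinates.
#' @param mrna_length mRNA length in nt.
#' @return List with `utr5 = c(0, cds$start)` and
#'   `utr3 = c(cds$end, mrna_length)` half-open intervals (possibly empty).
#' @export
extract_utrs <- function(cds, mrna_length) {
  if (cds$start < 0 || cds$end > mrna_length) stop("CDS out of bounds")
  list(utr5 = c(0, cds$start), utr3 = c(cds$end, mrna_length))
}

interval_len <- function(iv) max(0, iv[2L] - iv[1L])
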