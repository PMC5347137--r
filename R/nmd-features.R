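# NMD-relevant feature classification: PTC status by the 50-nt junction
# rule, uORF presence in the 5' UTR, and 3' UTR length category.

#' Annotate premature-termination-codon status (50-nt rule)
#'
#' A stop codon marks its transcript as PTC-containing when it lies more
#' than `min_distance` nt (strictly) upstream of the final exon-exon
#' junction. The distance is `last_junction - cds_end` in mRNA
#' coordinates, i.e. the number of nt from the first base after the stop
#' codon to the first base after the final junction. Single-exon
#' transcripts have no junction and are never PTC-positive.
#'
#' @param cds A `cds_annotation` (see [select_cds()]).
#' @param map The transcript's `mrna_map`.
#' @param min_distance Strict threshold in nt; default 50.
#' @return List `has_ptc` (flag) and `distance` (nt, `NA` for single-exon
#'   transcripts; negative when the stop lies downstream of the final
#'   junction).
#' @export
annotate_ptc <- function(cds, map, min_distance = 50) {
  if (cds$cds$end > map$mrna_length) stop("CDS end beyond mRNA length")
  if (length(map$junctions) == 0L)
    return(list(has_ptc = FALSE, distance = NA_real_))
  last_j <- max(map$junctions)
  d <- last_j - cds$cds$end
  list(has_ptc = d > min_distance, distance = d)
}

#' Detect upstream ORFs in a 5' UTR
#'
#' uORFs are complete ORFs (ATG...stop) fully contained in the 5' UTR.
#' The longest uORF's reading frame is compared with the CDS frame; by
#' default the frame-match flag is bookkeeping only and does not gate
#' `has_uorf` (set `frame_match_required = TRUE` for the stricter
#' reading).
#'
#' @param utr5_seq The 5' UTR sequence (mRNA positions `[0, cds_start)`).
#' @param cds_frame_offset `cds_start %% 3` of the transcript.
#' @param min_len Minimum ORF length in nt (default 3, see
#'   [find_complete_orfs()]).
#' @param all_starts Enumerate nested ATGs.
#' @param frame_match_required Require the longest uORF to share the CDS
#'   reading frame for `has_uorf` to be set.
#' @return List: `uorfs` (data.frame), `uorf_count`, `has_uorf`,
#'   `longest_uorf_len`, `uorf_in_cds_frame`.
#' @export
detect_uorfs <- function(utr5_seq, cds_frame_offset, min_len = 3L,
                         all_starts = FALSE, frame_match_required = FALSE) {
  orfs <- if (nchar(utr5_seq) >= 6L)
    find_complete_orfs(utr5_seq, min_len = min_len, all_starts = all_starts)
  else
    find_complete_orfs("", min_len = min_len)
  n <- nrow(orfs)
  if (n == 0L) {
    return(list(uorfs = orfs, uorf_count = 0L, has_uorf = FALSE,
                longest_uorf_len = 0L, uorf_in_cds_frame = FALSE))
  }
  longest <- orfs[which.max(orfs$length), ]
  # utr5 starts at mRNA position 0, so utr5-local coordinates are mRNA
  # coordinates and frames compare directly
  in_frame <- (longest$start %% 3L) == (cds_frame_offset %% 3L)
  has <- if (frame_match_required) in_frame else TRUE
  list(uorfs = orfs, uorf_count = n, has_uorf = has,
       longest_uorf_len = longest$length, uorf_in_cds_frame = in_frame)
}

#' Categorize a 3' UTR by length
#'
#' Boundaries follow the standard three-class convention:
#' short `<= 350` nt, long `>= 1500` nt, medium in between.
#'
#' @param utr3_len Length(s) in nt, `>= 0`.
#' @param short_max,long_min Class boundaries in nt.
#' @return Character vector in `{"short","medium","long"}`.
#' @export
utr3_category <- function(utr3_len, short_max = 350, long_min = 1500) {
  if (any(utr3_len < 0)) stop("negative 3' UTR length")
  ifelse(utr3_len <= short_max, "short",
         ifelse(utr3_len >= long_min, "long", "medium"))
}

#' Annotate NMD-relevant features for a set of transcripts
#'
#' Runs, per transcript: spliced-sequence construction, complete-ORF
#' discovery, CDS selection (longest ORF), PTC annotation by the 50-nt
#' rule, uORF detection in the 5' UTR, and 3' UTR categorization.
#' Transcripts without a complete ORF are skipped and listed (with a
#' reason) in the `"skipped"` attribute.
#'
#' @param ts List of transcript models (biotype-filtered).
#' @param genome An `nmd_genome`.
#' @param min_len Minimum ORF length in nt.
#' @param uorf_all_starts Enumerate nested uORF start codons.
#' @param uorf_frame_match Require CDS-frame match for `has_uorf`.
#' @param ptc_min_distance Strict PTC distance threshold in nt.
#' @param utr3_short_max,utr3_long_min 3' UTR class boundaries in nt.
#' @return `data.frame`, one row per annotatable transcript, with fields
#'   `transcript_id`, `gene_id`, `mrna_length`, `n_exons`, `cds_start`,
#'   `cds_end`, `utr5_len`, `utr3_len`, `utr3_category`, `has_ptc`,
#'   `stop_to_last_junction`, `uorf_count`, `has_uorf`,
#'   `longest_uorf_len`, `uorf_in_cds_frame`, `n_overlapping_orfs`,
#'   `n_orfs`. Attribute `skipped`: data.frame of transcripts without a
#'   complete ORF.
#' @export
annotate_all <- function(ts, genome, min_len = 3L, uorf_all_starts = FALSE,
                         uorf_frame_match = FALSE, ptc_min_distance = 50,
                         utr3_short_max = 350, utr3_long_min = 1500) {
  rows <- vector("list", length(ts))
  skipped <- list()
  for (i in seq_along(ts)) {
    t <- ts[[i]]
    built <- build_mrna_map(t, genome)
    orfs <- find_complete_orfs(built$seq, min_len = min_len)
    cds <- select_cds(orfs, built$map$mrna_length, t$transcript_id)
    if (is.null(cds)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(transcript_id = t$transcript_id, reason = "no_complete_orf")
      next
    }
    ptc <- annotate_ptc(cds, built$map, min_distance = ptc_min_distance)
    utr5_seq <- if (cds$cds$start > 0) substr(built$seq, 1L, cds$cds$start) else ""
    uo <- detect_uorfs(utr5_seq, cds$cds$start %% 3L, min_len = min_len,
                       all_starts = uorf_all_starts,
                       frame_match_required = uorf_frame_match)
    # ORFs starting in the 5' UTR but terminating at/after the CDS start:
    # counted separately, never set has_uorf
    n_overlap <- sum(orfs$start < cds$cds$start & orfs$end > cds$cds$start)
    utr3_len <- interval_len(cds$utr3)
    rows[[i]] <- data.frame(
      transcript_id = t$transcript_id,
      gene_id = t$gene_id,
      mrna_length = built$map$mrna_length,
      n_exons = nrow(t$exons),
      cds_start = cds$cds$start,
      cds_end = cds$cds$end,
      utr5_len = interval_len(cds$utr5),
      utr3_len = utr3_len,
      utr3_category = utr3_category(utr3_len, utr3_short_max, utr3_long_min),
      has_ptc = ptc$has_ptc,
      stop_to_last_junction = ptc$distance,
      uorf_count = uo$uorf_count,
      has_uorf = uo$has_uorf,
      longest_uorf_len = uo$longest_uorf_len,
      uorf_in_cds_frame = uo$uorf_in_cds_frame,
      n_overlapping_orfs = n_overlap,
      n_orfs = nrow(orfs),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(transcript_id = character(0), reason = character(0))
  out
}
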