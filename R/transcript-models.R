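# Genome and transcript-model ingestion: FASTA genomes, GTF exon structures,
# spliced-mRNA coordinate maps, and the RNA-type (biotype) filter.
#
# Conventions: all internal coordinates are 0-based, half-open. GTF I/O
# converts from/to the format's 1-based inclusive intervals. Exon lists are
# stored in transcript 5'->3' order, i.e. descending genomic coordinate on
# the minus strand.

#' Read a genome FASTA into a named sequence set
#'
#' @param path Path to a FASTA file. Each record becomes one chromosome;
#'   the chromosome name is the first whitespace-delimited token of the
#'   header. Sequences are uppercased; the alphabet is restricted to
#'   A, C, G, T, N.
#' @return A named character vector of chromosome sequences, class
#'   `nmd_genome`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(dss) == 0L) stop("FASTA '", path, "' contains no records")
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names in ", path)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  structure(seqs, class = "nmd_genome")
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 0-based half-open genomic intervals,
#'   rows ordered in transcript 5'->3' direction (descending genomic start
#'   on the minus strand).
#' @param biotype Annotation class, e.g. `"protein_coding"`; `"unknown"`
#'   when the source annotation carries none.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "unknown") {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, ": no exons")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": empty or inverted exon")
  o <- order(exons[, 1L])
  if (nrow(exons) > 1L) {
    sorted <- exons[o, , drop = FALSE]
    if (any(sorted[-nrow(sorted), 2L] > sorted[-1L, 1L]))
      stop("transcript ", transcript_id, ": overlapping exons")
    # enforce 5'->3' storage order
    exons <- if (strand == "+") exons[o, , drop = FALSE]
             else exons[rev(o), , drop = FALSE]
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, biotype = biotype),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d exon(s), %d nt spliced, biotype=%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$exons[, 2L] - x$exons[, 1L]), x$biotype))
  invisible(x)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used. Exons are grouped by `transcript_id`;
#' the biotype is taken from the first attribute present among
#' `biotype_attrs` (transcripts without one are labelled `"unknown"` and
#' will be dropped by [filter_biotypes()]).
#'
#' @param path GTF file path.
#' @param biotype_attrs Attribute keys searched, in order, for the biotype.
#' @return Named list of [transcript_model()] objects.
#' @export
read_gtf <- function(path, biotype_attrs = c("transcript_biotype", "gene_biotype")) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  is_exon <- !is.na(mc$type) & mc$type == "exon"
  if (!any(is_exon)) stop("GTF '", path, "' contains no exon features")
  ex <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    stringsAsFactors = FALSE
  )
  ex$transcript_id <- if ("transcript_id" %in% names(mc))
    mc$transcript_id[is_exon] else NA_character_
  ex$gene_id <- if ("gene_id" %in% names(mc)) mc$gene_id[is_exon] else NA_character_
  if (anyNA(ex$transcript_id))
    stop("GTF '", path, "': exon feature(s) missing transcript_id")
  bt <- rep(NA_character_, nrow(ex))
  for (key in biotype_attrs) {
    if (key %in% names(mc)) {
      v <- mc[[key]][is_exon]
      bt <- ifelse(is.na(bt) & !is.na(v), v, bt)
    }
  }
  ex$biotype <- ifelse(is.na(bt), "unknown", bt)

  out <- lapply(split(seq_len(nrow(ex)), ex$transcript_id), function(i) {
    rows <- ex[i, , drop = FALSE]
    strand <- rows$strand[1L]
    if (!strand %in% c("+", "-"))
      stop("transcript ", rows$transcript_id[1L], ": unstranded exons")
    transcript_model(
      transcript_id = rows$transcript_id[1L],
      gene_id = rows$gene_id[1L],
      chrom = rows$chrom[1L],
      strand = strand,
      exons = cbind(rows$start, rows$end),
      biotype = rows$biotype[1L]
    )
  })
  out[order(names(out))]
}

#' Retain protein-coding transcripts only
#'
#' Mirrors the RNA-type filter applied before NMD-feature annotation:
#' rRNA, tRNA, snRNA, snoRNA, ncRNA, pseudogene and unknown-biotype
#' transcripts are removed. Removal counts per biotype are attached as the
#' `"removed"` attribute.
#'
#' @param ts List of transcript models.
#' @param keep Biotypes retained (default `"protein_coding"`).
#' @return Filtered list with a `removed` attribute (named integer vector).
#' @export
filter_biotypes <- function(ts, keep = "protein_coding") {
  bt <- vapply(ts, function(t) t$biotype, character(1))
  kept <- ts[bt %in% keep]
  removed <- table(bt[!bt %in% keep])
  structure(kept, removed = c(removed))
}

revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Build the spliced mRNA sequence and coordinate map of a transcript
#'
#' Concatenates exon sequences in transcript 5'->3' order (reverse
#' complementing on the minus strand) and records, for each exon, its mRNA
#' interval so that mRNA and genomic coordinates can be interconverted.
#' Junction `i` is the mRNA coordinate of the first base *after* the i-th
#' exon-exon junction, i.e. the cumulative length of the first `i` exons.
#'
#' @param t A [transcript_model()].
#' @param genome An `nmd_genome` (named character vector).
#' @return List with elements `seq` (spliced mRNA string) and `map` (class
#'   `mrna_map`: `transcript_id`, `mrna_length`, `junctions`, per-exon
#'   coordinate table).
#' @export
build_mrna_map <- function(t, genome) {
  if (!t$chrom %in% names(genome))
    stop("transcript ", t$transcript_id, ": chromosome ", t$chrom,
         " absent from genome")
  chrom_seq <- genome[[t$chrom]]
  clen <- nchar(chrom_seq)
  if (any(t$exons[, 1L] < 0) || any(t$exons[, 2L] > clen))
    stop("transcript ", t$transcript_id, ": exon outside chromosome bounds")
  widths <- t$exons[, 2L] - t$exons[, 1L]
  pieces <- substring(chrom_seq, t$exons[, 1L] + 1L, t$exons[, 2L])
  if (t$strand == "-") pieces <- revcomp(pieces)
  seq <- paste(pieces, collapse = "")
  m_end <- cumsum(widths)
  m_start <- m_end - widths
  map <- structure(
    list(
      transcript_id = t$transcript_id,
      strand = t$strand,
      mrna_length = sum(widths),
      junctions = if (length(widths) > 1L) m_end[-length(m_end)] else numeric(0),
      exon_table = data.frame(m_start = m_start, m_end = m_end,
                              g_start = t$exons[, 1L], g_end = t$exons[, 2L])
    ),
    class = "mrna_map"
  )
  list(seq = seq, map = map)
}

#' Convert mRNA coordinates to genomic coordinates
#'
#' @param map An `mrna_map`.
#' @param pos 0-based mRNA position(s) in `[0, mrna_length)`.
#' @return 0-based genomic position(s).
#' @export
mrna_to_genomic <- function(map, pos) {
  if (any(pos < 0 | pos >= map$mrna_length)) stop("mRNA position out of range")
  et <- map$exon_table
  idx <- findInterval(pos, et$m_start)
  off <- pos - et$m_start[idx]
  if (map$strand == "+") et$g_start[idx] + off else et$g_end[idx] - 1 - off
}

#' Convert genomic coordinates to mRNA coordinates
#'
#' @param map An `mrna_map`.
#' @param gpos 0-based genomic position(s); must fall inside an exon.
#' @return 0-based mRNA position(s).
#' @export
genomic_to_mrna <- function(map, gpos) {
  et <- map$exon_table
  vapply(gpos, function(g) {
    hit <- which(g >= et$g_start & g < et$g_end)
    if (length(hit) != 1L) stop("genomic position ", g, " not exonic")
    off <- g - et$g_start[hit]
    if (map$strand == "+") et$m_start[hit] + off
    else et$m_start[hit] + (et$g_end[hit] - 1 - g)
  }, numeric(1))
}
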