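# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (character-by-character, codon-pair enumeration) so
# they share no code path with the implementation they check.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# every ATG walked codon-by-codon to its first in-frame stop
oracle_orfs <- function(seq, min_len = 3, all_starts = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  i <- 1
  while (i + 2 <= n) {
    if (substr(seq, i, i + 2) == "ATG") {
      j <- i
      while (j + 2 <= n) {
        cod <- substr(seq, j, j + 2)
        if (j > i && cod %in% stops) {
          rows[[length(rows) + 1]] <-
            data.frame(start = as.integer(i - 1), end = as.integer(j + 2),
                       length = as.integer(j + 2 - i + 1),
                       frame = as.integer((i - 1) %% 3))
          break
        }
        j <- j + 3
      }
    }
    i <- i + 1
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               frame = integer(0))
  out <- out[out$length >= max(min_len, 6), , drop = FALSE]
  if (!all_starts && nrow(out)) {
    # keep the 5'-most start per (frame, stop)
    out <- out[order(out$start), , drop = FALSE]
    out <- out[!duplicated(paste(out$frame, out$end)), , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# exhaustive log-rank permutation p: all relabelings of group membership
oracle_logrank_perm <- function(records, groupA, groupB) {
  obs <- logrank_test(records, groupA, groupB)$chi2
  nA <- sum(records$group == groupA)
  combos <- utils::combn(nrow(records), nA)
  chis <- apply(combos, 2, function(idx) {
    r <- records
    r$group <- groupB
    r$group[idx] <- groupA
    logrank_test(r, groupA, groupB)$chi2
  })
  mean(chis >= obs - 1e-9)
}

# direct product-limit computation by hand (deaths before censorings)
oracle_km <- function(day, is_death) {
  o <- order(day)
  day <- day[o]; is_death <- is_death[o]
  times <- sort(unique(day[is_death]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    at_risk <- sum(day >= times[i])
    d <- sum(day == times[i] & is_death)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = times, surv = out)
}

make_tmpdir <- function() {
  d <- tempfile("nmdpipe_test_")
  dir.create(d)
  d
}

write_fixture_fasta <- function(seqs, path) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# minimal GTF writer for fixtures (1-based inclusive coordinates)
write_fixture_gtf <- function(rows, path) {
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            r$chrom, r$start1, r$end1, r$strand, r$gene_id, r$transcript_id,
            r$biotype)
  }, character(1))
  writeLines(lines, path)
  path
}

# assemble a transcript model + tiny genome with prescribed mRNA and
# junction layout (plus strand, contiguous exons with 20 nt introns)
plant_transcript <- function(mrna, junctions, id = "t1") {
  bounds <- c(0, junctions, nchar(mrna))
  segs <- substring(mrna, bounds[-length(bounds)] + 1, bounds[-1])
  chrom <- ""
  exons <- matrix(0, nrow = length(segs), ncol = 2)
  pos <- 0
  for (i in seq_along(segs)) {
    exons[i, ] <- c(pos, pos + nchar(segs[i]))
    chrom <- paste0(chrom, segs[i])
    pos <- pos + nchar(segs[i])
    if (i < length(segs)) {
      chrom <- paste0(chrom, strrep("C", 20))
      pos <- pos + 20
    }
  }
  genome <- structure(c(chr1 = chrom), class = "nmd_genome")
  t <- transcript_model(id, paste0("g_", id), "chr1", "+", exons,
                        biotype = "protein_coding")
  list(t = t, genome = genome)
}
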