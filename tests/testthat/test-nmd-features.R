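# PTC 50-nt rule, uORF detection, 3' UTR classes, full annotation.

# an mRNA whose CDS stop lands `dist` nt upstream of the final junction:
# utr5 60 nt, CDS 60 nt, utr3 long enough to host the junction
ptc_fixture <- function(dist, extra_utr3 = 100) {
  utr5 <- paste0(strrep("C", 58), "CC")
  cds <- paste0("ATG", strrep("GGC", 17), "TAA")  # 57 + 3 = 60 nt, wait: 3+51+3
  mrna <- paste0(utr5, cds, strrep("C", dist + extra_utr3))
  cds_end <- nchar(utr5) + nchar(cds)
  plant_transcript(mrna, junctions = cds_end + dist)
}

test_that("PTC boundary is strict: 50 nt is negative, 51 positive", {
  for (dist in c(49, 50, 51, 52)) {
    px <- ptc_fixture(dist)
    bm <- build_mrna_map(px$t, px$genome)
    cds <- select_cds(find_complete_orfs(bm$seq), bm$map$mrna_length)
    ptc <- annotate_ptc(cds, bm$map)
    expect_equal(ptc$distance, dist)
    expect_equal(ptc$has_ptc, dist > 50, info = paste("dist", dist))
  }
})

test_that("single-exon transcripts are never PTC-positive", {
  px <- plant_transcript(paste0(strrep("C", 60), "ATG", strrep("GGC", 30),
                                "TAA", strrep("C", 200)), junctions = numeric(0))
  bm <- build_mrna_map(px$t, px$genome)
  cds <- select_cds(find_complete_orfs(bm$seq), bm$map$mrna_length)
  ptc <- annotate_ptc(cds, bm$map)
  expect_false(ptc$has_ptc)
  expect_true(is.na(ptc$distance))
})

test_that("a junction upstream of the stop gives a negative distance, not PTC", {
  utr5 <- strrep("C", 60)
  cds <- paste0("ATG", strrep("GGC", 30), "TAA")
  mrna <- paste0(utr5, cds, strrep("C", 200))
  px <- plant_transcript(mrna, junctions = 70)  # inside the CDS
  bm <- build_mrna_map(px$t, px$genome)
  cds_a <- select_cds(find_complete_orfs(bm$seq), bm$map$mrna_length)
  ptc <- annotate_ptc(cds_a, bm$map)
  expect_lt(ptc$distance, 0)
  expect_false(ptc$has_ptc)
})

test_that("detect_uorfs finds contained uORFs and frame bookkeeping", {
  # minimal uORF
  r <- detect_uorfs("ATGTAA", cds_frame_offset = 0)
  expect_true(r$has_uorf)
  expect_equal(r$uorf_count, 1)
  expect_equal(r$longest_uorf_len, 6)
  expect_true(r$uorf_in_cds_frame)  # start 0 vs offset 0

  # no ATG
  r2 <- detect_uorfs("CCCCCCTAA", cds_frame_offset = 0)
  expect_false(r2$has_uorf)
  expect_equal(r2$longest_uorf_len, 0)

  # frame mismatch: uORF at 0, CDS offset 1
  r3 <- detect_uorfs("ATGTAACC", cds_frame_offset = 1)
  expect_true(r3$has_uorf)           # default: frame not required
  expect_false(r3$uorf_in_cds_frame)
  r4 <- detect_uorfs("ATGTAACC", cds_frame_offset = 1,
                     frame_match_required = TRUE)
  expect_false(r4$has_uorf)
})

test_that("uORF sets equal the brute-force oracle on random UTRs", {
  set.seed(77)
  for (i in 1:60) {
    utr <- random_dna(300)
    r <- detect_uorfs(utr, cds_frame_offset = 0)
    want <- oracle_orfs(utr)
    expect_equal(r$uorfs, want, info = paste("utr", i))
    expect_equal(r$uorf_count, nrow(want))
    expect_equal(r$longest_uorf_len,
                 if (nrow(want)) max(want$length) else 0L)
  }
})

test_that("utr3_category boundaries are pinned", {
  expect_equal(utr3_category(350), "short")
  expect_equal(utr3_category(351), "medium")
  expect_equal(utr3_category(1499), "medium")
  expect_equal(utr3_category(1500), "long")
  expect_equal(utr3_category(0), "short")
  expect_equal(utr3_category(c(10, 800, 2000)), c("short", "medium", "long"))
  expect_error(utr3_category(-1), "negative")
})

test_that("annotate_all recovers planted features and is idempotent", {
  spec <- synthetic_spec(seed = 7, n_transcripts = 100, n_nmd_targets = 20)
  g <- gen_genome_and_transcripts(spec)
  coding <- filter_biotypes(g$transcripts)
  f1 <- annotate_all(coding, g$genome)
  f2 <- annotate_all(coding, g$genome)
  expect_identical(f1, f2)
  m <- match(g$truth$transcript_id, f1$transcript_id)
  expect_false(anyNA(m))
  expect_equal(f1$has_ptc[m], g$truth$has_ptc)
  expect_equal(sum(f1$has_ptc), round(100 * spec$frac_ptc))
  expect_equal(f1$has_uorf[m], g$truth$has_uorf)
  expect_equal(f1$utr3_category[m], g$truth$utr3_category)
  expect_equal(f1$cds_start[m], g$truth$cds_start)
  expect_equal(f1$cds_end[m], g$truth$cds_end)
})

test_that("all-single-exon input yields zero PTC calls", {
  mk <- function(i) {
    mrna <- paste0(strrep("C", 30), "ATG", strrep("GGC", 20), "TAA",
                   strrep("C", 120))
    plant_transcript(mrna, numeric(0), id = paste0("s", i))
  }
  ps <- lapply(1:5, mk)
  genome <- structure(
    stats::setNames(vapply(ps, function(p) p$genome[["chr1"]], character(1)),
                    paste0("c", 1:5)),
    class = "nmd_genome")
  ts <- lapply(seq_along(ps), function(i) {
    t <- ps[[i]]$t; t$chrom <- paste0("c", i); t
  })
  f <- annotate_all(ts, genome)
  expect_equal(sum(f$has_ptc), 0)
  expect_true(all(is.na(f$stop_to_last_junction)))
})

test_that("extending the 3'-most exon never flips PTC and never shrinks the 3' UTR", {
  set.seed(13)
  spec <- synthetic_spec(seed = 13, n_transcripts = 20, n_nmd_targets = 5)
  g <- gen_genome_and_transcripts(spec)
  coding <- filter_biotypes(g$transcripts)
  base <- annotate_all(coding, g$genome)
  # extend each transcript's 3'-most exon by 30 nt where the chromosome allows
  ext <- lapply(coding, function(t) {
    if (t$strand == "+") {
      i <- which.max(t$exons[, 2])
      if (t$exons[i, 2] + 30 <= nchar(g$genome[[t$chrom]]))
        t$exons[i, 2] <- t$exons[i, 2] + 30
    } else {
      i <- which.min(t$exons[, 1])
      if (t$exons[i, 1] - 30 >= 0) t$exons[i, 1] <- t$exons[i, 1] - 30
    }
    t
  })
  extended <- annotate_all(ext, g$genome)
  m <- match(base$transcript_id, extended$transcript_id)
  expect_equal(extended$has_ptc[m], base$has_ptc)
  expect_true(all(extended$utr3_len[m] >= base$utr3_len))
})
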