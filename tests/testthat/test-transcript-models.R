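# Genome/GTF ingestion, spliced-map arithmetic and the biotype filter.

test_that("read_genome_fasta normalizes, validates and errors on degenerate input", {
  d <- make_tmpdir()
  fa <- write_fixture_fasta(
    list(chrI = strrep("ACGT", 250), chrII = strrep("acgtn", 100)),
    file.path(d, "g.fa"))
  g <- read_genome_fasta(fa)
  expect_s3_class(g, "nmd_genome")
  expect_named(g, c("chrI", "chrII"))
  expect_equal(nchar(g[["chrI"]]), 1000)
  expect_equal(nchar(g[["chrII"]]), 500)
  expect_equal(g[["chrII"]], strrep("ACGTN", 100))  # uppercased, N kept

  empty <- file.path(d, "empty.fa"); file.create(empty)
  expect_error(read_genome_fasta(empty), "no records")
  expect_error(read_genome_fasta(file.path(d, "absent.fa")), "not found")
})

test_that("read_gtf groups exons per transcript with strand-aware 5'->3' order", {
  d <- make_tmpdir()
  rows <- data.frame(
    chrom = "chr1",
    start1 = c(1, 101, 201, 301, 401, 1, 101),
    end1 = c(50, 150, 250, 350, 450, 60, 160),
    strand = c("+", "+", "+", "-", "-", "+", "+"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC", "gC"),
    transcript_id = c("tA", "tA", "tA", "tB", "tB", "tC1", "tC2"),
    biotype = "protein_coding")
  # two transcripts of one gene
  rows$gene_id[6:7] <- "gC"; rows$transcript_id[6] <- "tC1"; rows$transcript_id[7] <- "tC2"
  gtf <- write_fixture_gtf(rows, file.path(d, "a.gtf"))
  ts <- read_gtf(gtf)
  expect_setequal(names(ts), c("tA", "tB", "tC1", "tC2"))
  # plus strand: ascending genomic order
  expect_equal(ts$tA$exons[, 1], c(0, 100, 200))
  # minus strand: exon with larger genomic start first
  expect_equal(ts$tB$exons[, 1], c(400, 300))
  expect_equal(ts$tC1$gene_id, ts$tC2$gene_id)
})

test_that("read_gtf rejects overlapping exons and missing transcript_id", {
  d <- make_tmpdir()
  rows <- data.frame(chrom = "chr1", start1 = c(1, 40), end1 = c(50, 90),
                     strand = "+", gene_id = "g", transcript_id = "t",
                     biotype = "x")
  gtf <- write_fixture_gtf(rows, file.path(d, "bad.gtf"))
  expect_error(read_gtf(gtf), "overlapping")
  writeLines('chr1\tsrc\texon\t1\t50\t.\t+\t.\tgene_id "g";',
             file.path(d, "noid.gtf"))
  expect_error(read_gtf(file.path(d, "noid.gtf")), "transcript_id")
})

test_that("build_mrna_map computes lengths, junctions and reverse complement", {
  genome <- structure(c(chr1 = strrep("ACGT", 100)), class = "nmd_genome")
  t <- transcript_model("t1", "g1", "chr1", "+",
                        rbind(c(0, 100), c(150, 200)))
  bm <- build_mrna_map(t, genome)
  expect_equal(bm$map$mrna_length, 150)
  expect_equal(bm$map$junctions, 100)
  expect_equal(nchar(bm$seq), 150)

  t1 <- transcript_model("t2", "g2", "chr1", "+", rbind(c(0, 80)))
  expect_length(build_mrna_map(t1, genome)$map$junctions, 0)

  gm <- structure(c(c2 = "ATGC"), class = "nmd_genome")
  tm <- transcript_model("t3", "g3", "c2", "-", rbind(c(0, 4)))
  expect_equal(build_mrna_map(tm, gm)$seq, "GCAT")

  tbad <- transcript_model("t4", "g4", "chr1", "+", rbind(c(390, 450)))
  expect_error(build_mrna_map(tbad, genome), "bounds")
})

test_that("mRNA<->genome round trip is the identity and splice matches a base-wise oracle", {
  set.seed(11)
  genome <- structure(c(chrZ = random_dna(5000)), class = "nmd_genome")
  for (rep_i in 1:60) {
    n_ex <- sample(1:5, 1)
    starts <- sort(sample(0:4500, n_ex))
    ends <- pmin(starts + sample(20:80, n_ex, TRUE), 5000)
    ok <- c(TRUE, ends[-n_ex] < starts[-1])
    starts <- starts[ok]; ends <- ends[ok]; n_ex <- sum(ok)
    strand <- sample(c("+", "-"), 1)
    ex <- cbind(starts, ends)
    if (strand == "-") ex <- ex[rev(seq_len(n_ex)), , drop = FALSE]
    t <- transcript_model(paste0("r", rep_i), "g", "chrZ", strand, ex)
    bm <- build_mrna_map(t, genome)
    # conservation
    expect_equal(bm$map$mrna_length, sum(ends - starts))
    # round trip on every position
    pos <- seq_len(bm$map$mrna_length) - 1
    expect_equal(genomic_to_mrna(bm$map, mrna_to_genomic(bm$map, pos)), pos)
    # strand oracle: minus-strand splice == revcomp of plus-strand splice
    if (strand == "-") {
      tp <- transcript_model("p", "g", "chrZ", "+",
                             ex[rev(seq_len(n_ex)), , drop = FALSE])
      expect_equal(bm$seq, oracle_revcomp(build_mrna_map(tp, genome)$seq))
    }
  }
})

test_that("filter_biotypes keeps protein_coding only and logs removals", {
  mk <- function(id, bt) transcript_model(id, "g", "c", "+",
                                          rbind(c(0, 10)), biotype = bt)
  genomeless <- list(mk("a", "protein_coding"), mk("b", "rRNA"),
                     mk("c", "pseudogene"), mk("d", "protein_coding"))
  out <- filter_biotypes(genomeless)
  expect_length(out, 2)
  expect_equal(sort(attr(out, "removed")[c("rRNA", "pseudogene")]),
               sort(c(rRNA = 1L, pseudogene = 1L)))
  expect_length(filter_biotypes(list()), 0)
  all_pc <- filter_biotypes(genomeless[c(1, 4)])
  expect_length(all_pc, 2)
})
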