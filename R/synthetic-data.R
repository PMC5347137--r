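# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes -- genome FASTA, annotation GTF, expression table,
# decay time courses, survival tables -- can be generated from one
# SyntheticSpec, bit-reproducibly from its seed.
#
# Transcripts are constructed feature-first: the CDS, the stop-to-
# junction distance, the planted uORF and the 3' UTR length are placed to
# satisfy the requested class, rather than sampling sequences and
# labelling them afterwards. Sequence construction guarantees that the
# planted CDS is the uniquely longest complete ORF: outside the CDS start
# and the planted uORF, no ATG occurs anywhere in the mRNA (UTRs are
# scrubbed, CDS-internal and boundary-spanning ATGs are repaired), so the
# ORF set of every mRNA is exactly {CDS} or {CDS, uORF}.

#' Specification for the synthetic-data generators
#'
#' Defaults emulate the study design the pipeline targets: a four-
#' genotype expression contrast (wild type, a daf-2-like insulin/IGF-1
#' receptor mutant, an smg-2-like NMD-deficient mutant, and the double
#' mutant) measured in duplicate; strong down-regulation of NMD targets
#' in the daf-2-like mutant with smg-2-dependent restoration; DRB-chase
#' decay curves; and Weibull lifespans with ~10% censoring.
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the spec including this seed.
#' @param n_transcripts Number of protein-coding transcripts.
#' @param frac_ptc,frac_uorf,frac_long_utr3 Feature proportions (exact
#'   counts after rounding).
#' @param n_noncoding Decoy transcripts with non-coding biotypes (exercise
#'   the RNA-type filter).
#' @param n_nmd_targets Planted NMD targets (chosen among feature-bearing
#'   transcripts).
#' @param effect_down_log2fc Target effect in the daf-2-like mutant vs WT
#'   (log2 units; negative = depletion).
#' @param effect_restore_log2fc Target effect in the double mutant vs the
#'   daf-2-like mutant (restoration).
#' @param effect_mutb_log2fc Target effect in the smg-2-like mutant vs WT
#'   (targets accumulate when decay is lost).
#' @param noise_sd Per-replicate Gaussian log2 noise.
#' @param replicates Replicates per condition (2, mirroring duplicate
#'   RNA collections).
#' @param frac_bad_status Fraction of non-target records flagged
#'   NOTEST/HIDATA/FAIL; an equal fraction gets one zero-FPKM condition.
#' @param decay data.frame gene / genotype / t_half (minutes).
#' @param decay_timepoints Minutes after transcription shutoff.
#' @param decay_replicates Replicates per timepoint.
#' @param decay_noise_sd Lognormal noise s.d. (natural-log scale).
#' @param survival data.frame group / n / scale / shape / censor_frac
#'   (Weibull scale and shape in days).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    seed = 1L,
    n_transcripts = 1000L,
    frac_ptc = 0.2,
    frac_uorf = 0.2,
    frac_long_utr3 = 0.2,
    n_noncoding = 30L,
    n_nmd_targets = 200L,
    effect_down_log2fc = -2,
    effect_restore_log2fc = 2,
    effect_mutb_log2fc = 1,
    noise_sd = 0.25,
    replicates = 2L,
    frac_bad_status = 0.05,
    decay = data.frame(
      gene = rep(c("rpl-12.ptc", "rpl-7A.ptc"), each = 2),
      genotype = rep(c("WT", "daf2"), 2),
      t_half = c(60, 30, 80, 40)),
    decay_timepoints = c(0, 30, 60, 90, 120),
    decay_replicates = 3L,
    decay_noise_sd = 0.1,
    survival = data.frame(
      group = c("WT", "daf2"),
      n = c(100L, 100L),
      scale = c(17, 35),
      shape = c(4, 4),
      censor_frac = c(0.1, 0.1))) {
  fr <- c(frac_ptc, frac_uorf, frac_long_utr3)
  if (any(fr < 0 | fr > 1)) stop("feature fractions must lie in [0, 1]")
  if (any(survival$censor_frac >= 1)) stop("censor fraction must be < 1")
  if (any(survival$censor_frac < 0)) stop("censor fraction must be >= 0")
  structure(as.list(environment()), class = "synthetic_spec")
}

# --- sequence construction helpers -----------------------------------------

# sample() that never auto-expands a length-1 vector into 1:x
resample <- function(x, k) x[sample.int(length(x), k)]

rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# remove every ATG occurrence (CCG cannot recreate one with any neighbour)
scrub_atg <- function(s) {
  while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", "CCG", s, fixed = TRUE)
  s
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"), c("A","C","G","T")),
        1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))
# repair pool: no A at all, none start with TG => cannot take part in any
# ATG, and none is a stop codon
SAFE_CODONS <- c("CTG", "CCT", "GCT", "CGT", "CCG", "GGC", "CTC", "GTC")

# ATG + sense codons + stop, with no other ATG anywhere in the string
make_orf_seq <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 6)
  n_inner <- len_nt / 3 - 2L
  codons <- c("ATG",
              if (n_inner > 0) sample(SENSE_CODONS, n_inner, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1L))
  s <- paste(codons, collapse = "")
  repeat {
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
    hits <- hits[hits > 1L]
    if (length(hits) == 0L || hits[1L] == -1L) break
    ci <- unique(pmin((hits - 1L) %/% 3L + 1L, length(codons)))
    ci <- unique(c(ci, pmin(ci + 1L, length(codons))))
    ci <- setdiff(ci, c(1L, length(codons)))
    if (!length(ci)) break  # cannot happen: interior ATG implies interior codon
    for (j in ci) codons[j] <- sample(SAFE_CODONS, 1L)
    s <- paste(codons, collapse = "")
  }
  s
}

# uORF-free (or single-planted-uORF) UTR with ATG-proof boundaries
make_utr5 <- function(len, uorf_len = 0L) {
  s <- scrub_atg(rand_seq(len))
  if (len >= 2L) substr(s, len - 1L, len) <- "CC"  # block ATG spanning into CDS
  if (uorf_len > 0L) {
    stopifnot(len >= uorf_len + 4L)
    off <- sample.int(len - uorf_len - 3L, 1L) - 1L  # 0-based, leaves >= 2 nt tail
    substr(s, off + 1L, off + uorf_len) <- make_orf_seq(uorf_len)
    # block ATG spanning out of the uORF stop
    substr(s, off + uorf_len + 1L, off + uorf_len + 2L) <- "CC"
    attr(s, "uorf_start") <- off
  }
  s
}

make_utr3 <- function(len) {
  s <- scrub_atg(rand_seq(len))
  if (len >= 2L) substr(s, 1L, 2L) <- "CC"  # block ATG spanning from the stop
  s
}

# --- genome + transcript generator -----------------------------------------

#' Generate a synthetic genome, annotation and feature truth table
#'
#' Builds multi-exon transcripts feature-first (see module header), lays
#' them out with random introns across six chromosomes on both strands,
#' and optionally writes a FASTA, a GTF and a truth TSV. Boundary cases
#' are guaranteed: whenever the class counts allow, one PTC-positive
#' transcript has a stop-to-junction distance of exactly 51 nt and one
#' PTC-negative multi-exon transcript exactly 50 nt.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory; when `NULL` nothing is written.
#' @return List: `genome` (`nmd_genome`), `transcripts` (list of
#'   [transcript_model()]), `truth` (data.frame), and when `dir` is given
#'   `fasta`, `gtf`, `truth_path`.
#' @export
gen_genome_and_transcripts <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_transcripts

  n_ptc <- round(n * spec$frac_ptc)
  n_uorf <- round(n * spec$frac_uorf)
  n_long <- round(n * spec$frac_long_utr3)
  is_ptc <- logical(n); is_ptc[sample.int(n, n_ptc)] <- TRUE
  is_uorf <- logical(n); is_uorf[sample.int(n, n_uorf)] <- TRUE
  n_rest <- n - n_long
  cat_pool <- sample(c(rep("long", n_long),
                       rep("short", ceiling(n_rest / 2)),
                       rep("medium", floor(n_rest / 2))))
  # PTC+ transcripts need a junction inside the 3' UTR; keep them multi-exon
  single_exon <- !is_ptc & (stats::runif(n) < 0.25)
  ptc_neg_mode <- ifelse(is_ptc, "ptc",
                  ifelse(single_exon, "single",
                         sample(c("close", "before"), n, replace = TRUE)))
  forced51 <- which(is_ptc)[1]
  forced50 <- which(ptc_neg_mode == "close")[1]

  chroms <- paste0("chr", c("I", "II", "III", "IV", "V", "X"))
  pieces <- stats::setNames(vector("list", length(chroms)), chroms)
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  models <- vector("list", n + spec$n_noncoding)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    uorf_len <- if (is_uorf[i]) 3L * sample(3:8, 1L) else 0L
    utr5_len <- max(40L, uorf_len + 10L) + sample.int(120L, 1L)
    cds_len <- 3L * sample(100:250, 1L)
    utr3_len <- switch(cat_pool[i],
                       short = sample(60:350, 1L),
                       medium = sample(351:1499, 1L),
                       long = sample(1500:2500, 1L))
    utr5 <- make_utr5(utr5_len, uorf_len)
    uorf_start <- attr(utr5, "uorf_start")
    mrna <- paste0(utr5, make_orf_seq(cds_len), make_utr3(utr3_len))
    L <- nchar(mrna)
    cds_start <- utr5_len
    cds_end <- utr5_len + cds_len

    mode <- ptc_neg_mode[i]
    junctions <- numeric(0)
    if (mode != "single") {
      last_j <- switch(mode,
        ptc = cds_end + if (!is.na(forced51) && i == forced51) 51L else
          resample(51:min(utr3_len - 2L, 400L), 1L),
        close = cds_end + if (!is.na(forced50) && i == forced50) 50L else
          sample.int(min(50L, utr3_len - 2L), 1L),
        before = resample(seq(10L, cds_end - 10L), 1L))
      pool <- seq(5L, last_j - 5L)
      n_extra <- min(sample(0:2, 1L), length(pool))
      extra <- if (n_extra > 0) resample(pool, n_extra) else numeric(0)
      junctions <- sort(unique(c(extra, last_j)))
      junctions <- junctions[junctions > 0 & junctions < L]
    }

    # split the mRNA into exon segments and lay them on a chromosome
    bounds <- c(0, junctions, L)
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1L]
    segs <- substring(mrna, seg_start + 1L, seg_end)
    strand <- sample(c("+", "-"), 1L)
    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    g_segs <- if (strand == "+") segs else rev(revcomp(segs))
    n_ex <- length(g_segs)
    introns <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(z) rand_seq(sample(60:150, 1L)),
             character(1)) else character(0)
    gstart <- cursor[[chrom]]
    ex_g <- matrix(0, nrow = n_ex, ncol = 2L)
    pos <- gstart
    for (e in seq_len(n_ex)) {
      w <- nchar(g_segs[e])
      ex_g[e, ] <- c(pos, pos + w)
      pos <- pos + w
      if (e < n_ex) {
        pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- g_segs[e]
        pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- introns[e]
        pos <- pos + nchar(introns[e])
      } else {
        pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- g_segs[e]
      }
    }
    pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- rand_seq(200L)
    cursor[[chrom]] <- pos + 200L

    # 5'->3' exon order: ascending genomic for +, descending for -
    ex_ord <- if (strand == "+") ex_g else ex_g[rev(seq_len(n_ex)), , drop = FALSE]
    tid <- sprintf("t%04d", i)
    gid <- sprintf("g%04d", i)
    models[[i]] <- transcript_model(tid, gid, chrom, strand, ex_ord,
                                    biotype = "protein_coding")
    dist <- if (mode == "single") NA_real_ else max(junctions) - cds_end
    truth_rows[[i]] <- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      n_exons = n_ex, mrna_length = L,
      cds_start = cds_start, cds_end = cds_end,
      utr5_len = utr5_len, utr3_len = utr3_len,
      utr3_category = cat_pool[i],
      has_ptc = is_ptc[i], ptc_distance = dist,
      has_uorf = is_uorf[i],
      uorf_start = if (is_uorf[i]) uorf_start else NA_integer_,
      uorf_len = uorf_len,
      biotype = "protein_coding",
      stringsAsFactors = FALSE
    )
  }

  # non-coding decoys: single-exon, no planted ORF structure
  nc_biotypes <- c("rRNA", "tRNA", "snoRNA", "ncRNA", "pseudogene")
  for (j in seq_len(spec$n_noncoding)) {
    chrom <- chroms[(j - 1L) %% length(chroms) + 1L]
    w <- sample(200:600, 1L)
    s <- rand_seq(w)
    gstart <- cursor[[chrom]]
    pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- s
    pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- rand_seq(100L)
    cursor[[chrom]] <- gstart + w + 100L
    models[[n + j]] <- transcript_model(
      sprintf("nc%03d", j), sprintf("gnc%03d", j), chrom, "+",
      matrix(c(gstart, gstart + w), ncol = 2L),
      biotype = sample(nc_biotypes, 1L))
  }

  genome <- structure(
    vapply(pieces, function(p) paste(unlist(p), collapse = ""), character(1)),
    class = "nmd_genome")
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  out <- list(genome = genome, transcripts = models, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(dir, "genome.fa")
    dss <- Biostrings::DNAStringSet(unclass(genome))
    Biostrings::writeXStringSet(dss, fasta, width = 70L)
    gtf <- file.path(dir, "annotation.gtf")
    write_gtf(models, gtf, seed = spec$seed)
    truth_path <- file.path(dir, "truth.tsv")
    write_table_prov(truth, truth_path, seed = spec$seed)
    out$fasta <- fasta; out$gtf <- gtf; out$truth_path <- truth_path
  }
  out
}

# GTF emitter (1-based inclusive coordinates, exons ascending per transcript)
write_gtf <- function(models, path, seed = NA) {
  lines <- c(sprintf("#!nmdpipe synthetic annotation seed=%s", seed))
  for (m in models) {
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      m$gene_id, m$transcript_id, m$biotype)
    lines <- c(lines, sprintf(
      "%s\tnmdpipe\texon\t%d\t%d\t.\t%s\t.\t%s",
      m$chrom, as.integer(ex[, 1L]) + 1L, as.integer(ex[, 2L]),
      m$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

# --- expression generator ---------------------------------------------------

#' Generate a four-genotype expression table with planted NMD targets
#'
#' Baseline log2 abundances are N(5, 1.5). Planted targets are depleted
#' in the daf-2-like mutant (`effect_down_log2fc`), accumulate in the
#' smg-2-like mutant (`effect_mutb_log2fc`), and are restored in the
#' double mutant relative to the daf-2-like single
#' (`effect_restore_log2fc`). Per-replicate Gaussian log2 noise of
#' `noise_sd` is added; contrast log2 fold-changes are replicate-mean
#' differences and p-values come from two-sample t-tests (with zero
#' noise, p is 0 for any nonzero difference and 1 otherwise). A fraction
#' of non-target records gets a failing status or one zero-FPKM condition
#' to exercise the expression filter; planted targets always stay
#' testable.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Truth table from [gen_genome_and_transcripts()].
#' @param dir Optional output directory (`expression.tsv`).
#' @return Expression data.frame (conditions WT, daf2, smg2, smg2daf2;
#'   contrasts `daf2_vs_WT`, `smg2_vs_WT`, `smg2daf2_vs_daf2`) with an
#'   `is_nmd_target` column.
#' @export
gen_expression <- function(spec, truth, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- nrow(truth)
  feature_pos <- truth$has_ptc | truth$has_uorf | truth$utr3_category == "long"
  n_targets <- min(spec$n_nmd_targets, sum(feature_pos))
  target <- logical(n)
  target[resample(which(feature_pos), n_targets)] <- TRUE

  base <- stats::rnorm(n, mean = 5, sd = 1.5)
  mu <- list(
    WT = base,
    daf2 = base + ifelse(target, spec$effect_down_log2fc, 0),
    smg2 = base + ifelse(target, spec$effect_mutb_log2fc, 0))
  mu$smg2daf2 <- mu$daf2 + ifelse(target, spec$effect_restore_log2fc, 0)

  r <- spec$replicates
  reps <- lapply(mu, function(m)
    matrix(stats::rnorm(n * r, mean = m, sd = spec$noise_sd), nrow = n))

  contrast_stats <- function(m2, m1) {
    d <- rowMeans(m2) - rowMeans(m1)
    if (spec$noise_sd == 0) {
      p <- ifelse(abs(d) > 0, 0, 1)
    } else {
      v <- (apply(m1, 1L, stats::var) + apply(m2, 1L, stats::var)) / r
      df <- 2L * (r - 1L)
      tstat <- d / sqrt(pmax(v, .Machine$double.eps))
      p <- 2 * stats::pt(-abs(tstat), df = df)
    }
    list(log2fc = d, p = p)
  }
  c_daf2 <- contrast_stats(reps$daf2, reps$WT)
  c_smg2 <- contrast_stats(reps$smg2, reps$WT)
  c_double <- contrast_stats(reps$smg2daf2, reps$daf2)

  expr <- data.frame(
    transcript_id = truth$transcript_id,
    gene_id = truth$gene_id,
    status = "OK",
    fpkm_WT = 2^rowMeans(reps$WT),
    fpkm_daf2 = 2^rowMeans(reps$daf2),
    fpkm_smg2 = 2^rowMeans(reps$smg2),
    fpkm_smg2daf2 = 2^rowMeans(reps$smg2daf2),
    log2fc_daf2_vs_WT = c_daf2$log2fc, p_daf2_vs_WT = c_daf2$p,
    log2fc_smg2_vs_WT = c_smg2$log2fc, p_smg2_vs_WT = c_smg2$p,
    log2fc_smg2daf2_vs_daf2 = c_double$log2fc, p_smg2daf2_vs_daf2 = c_double$p,
    is_nmd_target = target,
    stringsAsFactors = FALSE
  )

  non_target <- which(!target)
  n_bad <- round(spec$frac_bad_status * n)
  if (n_bad > 0 && length(non_target) >= 2L * n_bad) {
    bad <- sample(non_target, 2L * n_bad)
    expr$status[bad[seq_len(n_bad)]] <-
      sample(c("NOTEST", "HIDATA", "FAIL"), n_bad, replace = TRUE)
    zero <- bad[(n_bad + 1L):(2L * n_bad)]
    expr$fpkm_daf2[zero] <- 0
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, "expression.tsv")
    write_table_prov(expr, path, seed = spec$seed)
    attr(expr, "path") <- path
  }
  expr
}

# --- decay generator --------------------------------------------------------

#' Generate DRB-chase decay time courses with known half-lives
#'
#' `abundance(t) = 2^(-t / t_half) * exp(noise)`, normalized per
#' replicate to its own t = 0 value (so t = 0 is exactly 1), matching the
#' reference-gene-then-baseline normalization order used for real
#' qRT-PCR chase data.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (`decay.csv`).
#' @return data.frame gene, genotype, time, replicate, abundance.
#' @export
gen_decay <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  tp <- spec$decay_timepoints
  stopifnot(0 %in% tp)
  rows <- list()
  for (i in seq_len(nrow(spec$decay))) {
    g <- spec$decay$gene[i]; gt <- spec$decay$genotype[i]
    th <- spec$decay$t_half[i]
    for (rep_i in seq_len(spec$decay_replicates)) {
      raw <- 2^(-tp / th) *
        exp(stats::rnorm(length(tp), sd = spec$decay_noise_sd))
      ab <- raw / raw[tp == 0]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, genotype = gt, time = tp, replicate = rep_i,
        abundance = ab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, "decay.csv")
    write_table_prov(out, path, seed = spec$seed, sep = ",")
    attr(out, "path") <- path
  }
  out
}

# --- survival generator -----------------------------------------------------

#' Generate censored lifespan tables with group hazard differences
#'
#' Death days are Weibull(shape, scale) per group; a stated fraction of
#' animals is independently right-censored at a uniform day before their
#' death (animals leaving observation). Days are rounded to integers
#' (minimum 1), matching scoring on transfer days.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (`survival.csv`).
#' @return data.frame animal_id, group, day, event.
#' @export
gen_survival <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  rows <- list()
  for (i in seq_len(nrow(spec$survival))) {
    g <- spec$survival$group[i]
    n <- spec$survival$n[i]
    death <- stats::rweibull(n, shape = spec$survival$shape[i],
                             scale = spec$survival$scale[i])
    censored <- stats::runif(n) < spec$survival$censor_frac[i]
    day <- ifelse(censored, stats::runif(n, 0, death), death)
    rows[[i]] <- data.frame(
      animal_id = sprintf("%s_%04d", g, seq_len(n)),
      group = g,
      day = pmax(1, round(day)),
      event = ifelse(censored, "censored", "death"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, "survival.csv")
    write_table_prov(out, path, seed = spec$seed, sep = ",")
    attr(out, "path") <- path
  }
  out
}
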