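# Expression-table filtering, differential classes, and the NMD-target
# enrichment / restoration / gene-set statistics.
#
# Expression tables are plain data.frames with columns: transcript_id,
# gene_id, status, fpkm_<condition>..., log2fc_<contrast>..., p_<contrast>...
# DE p-values are inputs (or synthetic); no dispersion model is fitted here.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param fragment_count Fragments assigned to the transcript.
#' @param transcript_length Spliced transcript length in nt (> 0).
#' @param total_mapped_fragments Library size in fragments (> 0).
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(fragment_count, transcript_length, total_mapped_fragments) {
  if (any(transcript_length <= 0)) stop("transcript length must be positive")
  if (any(total_mapped_fragments <= 0)) stop("total mapped fragments must be positive")
  fragment_count / ((transcript_length / 1e3) * (total_mapped_fragments / 1e6))
}

fpkm_columns <- function(expr) grep("^fpkm_", names(expr), value = TRUE)

#' Filter an expression table by test status and nonzero abundance
#'
#' Keeps records with status `OK` and FPKM strictly positive in every
#' condition; removal counts per reason are attached as the `"removed"`
#' attribute.
#'
#' @param expr Expression data.frame (see module header).
#' @return Filtered data.frame with a `removed` attribute.
#' @export
filter_expression <- function(expr) {
  fcols <- fpkm_columns(expr)
  if (!length(fcols)) stop("no fpkm_<condition> columns found")
  bad_status <- expr$status != "OK"
  zero_fpkm <- rowSums(as.matrix(expr[fcols]) <= 0) > 0
  keep <- !bad_status & !zero_fpkm
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- c(table(expr$status[bad_status]),
               zero_fpkm = sum(zero_fpkm & !bad_status))
  structure(out, removed = removed)
}

contrast_cols <- function(expr, contrast) {
  lc <- paste0("log2fc_", contrast)
  pc <- paste0("p_", contrast)
  if (!lc %in% names(expr) || !pc %in% names(expr))
    stop("contrast '", contrast, "' not present in expression table")
  list(log2fc = expr[[lc]], p = expr[[pc]])
}

#' Three-way differential-expression classification
#'
#' `down` when `log2fc <= -fc_threshold` and `p <= p_threshold`
#' (boundaries inclusive); `up` symmetrically; otherwise `unchanged`.
#' Defaults mirror the headline contrast thresholds (|log2fc| >= 1,
#' p <= 0.1); gene-ontology input lists use `fc_threshold = 0.4`.
#'
#' @param expr Expression data.frame.
#' @param contrast Contrast name (matching `log2fc_<contrast>` columns).
#' @param fc_threshold Absolute log2 fold-change threshold.
#' @param p_threshold p-value threshold.
#' @return data.frame `contrast`, `transcript_id`, `class`.
#' @export
classify_de <- function(expr, contrast, fc_threshold = 1, p_threshold = 0.1) {
  cc <- contrast_cols(expr, contrast)
  cls <- ifelse(cc$log2fc <= -fc_threshold & cc$p <= p_threshold, "down",
         ifelse(cc$log2fc >= fc_threshold & cc$p <= p_threshold, "up",
                "unchanged"))
  data.frame(contrast = contrast, transcript_id = expr$transcript_id,
             class = cls, stringsAsFactors = FALSE)
}

#' Chi-squared fraction test for feature enrichment among down genes
#'
#' Builds the 2x2 table (feature+/- x down/not-down) over the shared
#' transcript universe and applies Pearson's chi-squared test without
#' continuity correction (df = 1, two-sided). "Not-down" is all other
#' tested transcripts, so the reported fractions are per total
#' transcripts.
#'
#' @param de Output of [classify_de()].
#' @param features Feature table from [annotate_all()] (or any data.frame
#'   with `transcript_id` plus a logical feature column).
#' @param feature `"ptc"` or `"uorf"` (columns `has_ptc` / `has_uorf`).
#' @return List of class `nmd_enrichment`: `feature`, `contrast`, `table`
#'   (2x2), `chi2`, `p`, `fractions` (feature fraction among down /
#'   not-down), `untestable`.
#' @export
feature_fraction_test <- function(de, features, feature = c("ptc", "uorf")) {
  feature <- match.arg(feature)
  col <- c(ptc = "has_ptc", uorf = "has_uorf")[[feature]]
  idx <- match(de$transcript_id, features$transcript_id)
  shared <- !is.na(idx)
  has <- features[[col]][idx[shared]]
  down <- de$class[shared] == "down"
  tbl <- matrix(c(sum(has & down), sum(has & !down),
                  sum(!has & down), sum(!has & !down)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(feature = c("feature+", "feature-"),
                                de = c("down", "not_down")))
  untestable <- any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)
  if (untestable) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::chisq.test(tbl, correct = FALSE)
    chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
  }
  fractions <- c(down = tbl[1, 1] / sum(tbl[, 1]),
                 not_down = tbl[1, 2] / sum(tbl[, 2]))
  structure(list(feature = feature, contrast = de$contrast[1L], table = tbl,
                 chi2 = chi2, p = p, fractions = fractions,
                 untestable = untestable),
            class = "nmd_enrichment")
}

#' @export
print.nmd_enrichment <- function(x, ...) {
  cat(sprintf("<nmd_enrichment> %s vs DE class (%s)\n", x$feature, x$contrast))
  print(x$table)
  if (x$untestable) cat("untestable: a table margin is zero\n")
  else cat(sprintf("chi2 = %.4g, p = %.4g; fraction down = %.4f, not-down = %.4f\n",
                   x$chi2, x$p, x$fractions[1], x$fractions[2]))
  invisible(x)
}

#' Rank-sum (Wilcoxon/Mann-Whitney) two-sample test
#'
#' Normal approximation with tie and continuity corrections (the common
#' implementation default); when both samples have `n <= 10` an
#' exhaustive permutation of group labels is used instead
#' (`method = "auto"`).
#'
#' @param x,y Numeric samples.
#' @param method `"auto"`, `"normal"` or `"exact"`.
#' @return List `statistic` (Mann-Whitney U for `x`), `p.value`, `method`.
#' @export
ranksum_test <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("empty sample")
  if (method == "auto") method <- if (n1 <= 10L && n2 <= 10L) "exact" else "normal"
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "normal") {
    N <- n1 + n2
    tie_sizes <- table(r)
    v <- n1 * n2 / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
    z <- max(abs(U - mu) - 0.5, 0) / sqrt(v)  # continuity-corrected
    p <- if (v <= 0) 1 else min(1, 2 * stats::pnorm(-z))
  } else {
    combos <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  }
  list(statistic = U, p.value = p, method = method)
}

#' Fold-change comparison across 3' UTR length categories
#'
#' Pairwise two-sided rank-sum tests of per-transcript log2 fold-changes
#' between the long/medium/short 3' UTR classes, plus per-category
#' medians.
#'
#' @param expr Expression data.frame.
#' @param features Feature table with `utr3_category`.
#' @param contrast Contrast name.
#' @param method Passed to [ranksum_test()].
#' @return List: `medians`, `n`, `tests` (data.frame comparison/U/p),
#'   `skipped` (comparisons with a class of < 2 members).
#' @export
utr3_foldchange_test <- function(expr, features, contrast,
                                 method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  cc <- contrast_cols(expr, contrast)
  idx <- match(expr$transcript_id, features$transcript_id)
  shared <- !is.na(idx)
  cat3 <- features$utr3_category[idx[shared]]
  fc <- cc$log2fc[shared]
  groups <- split(fc, factor(cat3, levels = c("short", "medium", "long")))
  medians <- vapply(groups, stats::median, numeric(1))
  n <- vapply(groups, length, integer(1))
  pairs <- list(c("long", "short"), c("long", "medium"), c("medium", "short"))
  rows <- list(); skipped <- character(0)
  for (pr in pairs) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    lab <- paste(pr, collapse = "_vs_")
    if (length(a) < 2L || length(b) < 2L) {
      warning("category with < 2 members; skipping ", lab)
      skipped <- c(skipped, lab)
      next
    }
    rt <- ranksum_test(a, b, method = method)
    rows[[lab]] <- data.frame(comparison = lab, U = rt$statistic,
                              p = rt$p.value, method = rt$method)
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(0), U = numeric(0), p = numeric(0),
               method = character(0))
  rownames(tests) <- NULL
  list(medians = medians, n = n, tests = tests, skipped = skipped)
}

#' Restoration analysis across the four-genotype design
#'
#' Identifies transcripts down-regulated in the first contrast (mutant A
#' vs wild type) whose levels rise again in the double mutant relative to
#' mutant A: `restored = log2fc(double vs mutA) >= restore_threshold`.
#' The default threshold 0 counts any increase as restoration.
#'
#' @param expr Expression data.frame carrying both contrasts.
#' @param contrast_down Contrast defining down-regulation (e.g. mutA vs WT).
#' @param contrast_restore Contrast probing restoration (double vs mutA).
#' @param fc_threshold,p_threshold Down-class thresholds, see [classify_de()].
#' @param restore_threshold Restoration log2 fold-change threshold.
#' @param features Optional feature table; when given, restored fractions
#'   are summarized per feature class (`ptc`, `uorf`, `long_utr3`).
#' @return data.frame `transcript_id`, `down_in_mutA_vs_WT`,
#'   `restored_in_double_vs_mutA` (NA for transcripts not down); attribute
#'   `summary` with per-class restored fractions.
#' @export
restoration_analysis <- function(expr, contrast_down, contrast_restore,
                                 fc_threshold = 1, p_threshold = 0.1,
                                 restore_threshold = 0, features = NULL) {
  de <- classify_de(expr, contrast_down, fc_threshold, p_threshold)
  down <- de$class == "down"
  fc_rest <- contrast_cols(expr, contrast_restore)$log2fc
  restored <- ifelse(down, fc_rest >= restore_threshold, NA)
  out <- data.frame(transcript_id = expr$transcript_id,
                    down_in_mutA_vs_WT = down,
                    restored_in_double_vs_mutA = restored,
                    stringsAsFactors = FALSE)
  summ <- list(
    n_down = sum(down),
    n_restored = sum(restored, na.rm = TRUE),
    fraction_restored = if (sum(down)) mean(restored[down]) else NA_real_
  )
  if (!is.null(features)) {
    idx <- match(out$transcript_id, features$transcript_id)
    classes <- list(ptc = features$has_ptc[idx],
                    uorf = features$has_uorf[idx],
                    long_utr3 = features$utr3_category[idx] == "long")
    summ$by_class <- lapply(classes, function(cl) {
      sel <- down & !is.na(cl) & cl
      c(n_down = sum(sel),
        fraction_restored = if (sum(sel)) mean(restored[sel]) else NA_real_)
    })
  }
  structure(out, summary = summ)
}

#' Gene-set overrepresentation by hypergeometric tail and EASE score
#'
#' For each term, the one-sided Fisher p is the hypergeometric upper tail
#' P(X >= k) of the overlap; the EASE score recomputes the tail with
#' `k - 1`, a conservative "modified Fisher's exact test". Terms with no
#' overlap are skipped; term gene sets are intersected with the universe.
#'
#' @param target_set Character vector of target genes (subset of universe).
#' @param term_map data.frame `term_id`, `term_name`, `gene_id`.
#' @param universe Character vector of all tested genes.
#' @param bh Add Benjamini-Hochberg adjusted columns (off by default; the
#'   raw p-values mirror the primary reporting convention).
#' @return data.frame per term: `term_id`, `term_name`, `term_size`,
#'   `overlap`, `expected`, `p_fisher`, `p_ease`, sorted by `p_ease`.
#' @export
overrepresentation_test <- function(target_set, term_map, universe, bh = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  target <- intersect(unique(target_set), universe)
  N <- length(universe); n <- length(target)
  terms <- split(term_map$gene_id, term_map$term_id)
  term_names <- term_map$term_name[!duplicated(term_map$term_id)]
  names(term_names) <- term_map$term_id[!duplicated(term_map$term_id)]
  rows <- lapply(names(terms), function(tid) {
    genes <- intersect(unique(terms[[tid]]), universe)
    K <- length(genes)
    k <- length(intersect(genes, target))
    if (k == 0L) return(NULL)
    data.frame(
      term_id = tid,
      term_name = unname(term_names[tid]),
      term_size = K,
      overlap = k,
      expected = n * K / N,
      p_fisher = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      p_ease = stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      term_size = integer(0), overlap = integer(0),
                      expected = numeric(0), p_fisher = numeric(0),
                      p_ease = numeric(0)))
  if (bh) {
    out$p_fisher_bh <- stats::p.adjust(out$p_fisher, method = "BH")
    out$p_ease_bh <- stats::p.adjust(out$p_ease, method = "BH")
  }
  out <- out[order(out$p_ease, out$p_fisher), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of two gene sets against a common universe
#'
#' One-sided hypergeometric enrichment p for the observed overlap, with
#' fold = observed / expected overlap.
#'
#' @param setA,setB Character vectors (subsets of the universe).
#' @param universe Character vector of all genes.
#' @return List `overlap`, `expected`, `fold`, `p`.
#' @export
set_overlap_test <- function(setA, setB, universe) {
  universe <- unique(universe)
  a <- intersect(unique(setA), universe)
  b <- intersect(unique(setB), universe)
  N <- length(universe)
  if (!N) stop("empty universe")
  k <- length(intersect(a, b))
  if (!length(a) || !length(b))
    return(list(overlap = k, expected = 0, fold = NA_real_, p = 1))
  expected <- length(a) * length(b) / N
  list(overlap = k,
       expected = expected,
       fold = k / expected,
       p = stats::phyper(k - 1, length(a), N - length(a), length(b),
                         lower.tail = FALSE))
}
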