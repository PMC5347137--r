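# Pipeline orchestration: provenance-stamped output writers, a run
# configuration object whose defaults equal the published analysis
# parameters, stage commands, and a command-line dispatcher with
# subcommands annotate / enrich / halflife / survive / simulate / demo.

# 31-polynomial string hash mod 2^31-1; provenance tag, not cryptographic
config_hash <- function(x) {
  kv <- vapply(sort(names(x)), function(k)
    paste0(k, "=", paste(format(x[[k]], digits = 15), collapse = ",")),
    character(1))
  s <- paste(kv, collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# write a table with a provenance comment header; readable with
# read_table_prov(). Timestamps are omitted unless reproducible = FALSE.
write_table_prov <- function(df, path, seed = NA, config = NULL, sep = "\t",
                             reproducible = TRUE) {
  hdr <- sprintf("# nmdpipe seed=%s config=%s", seed,
                 if (is.null(config)) "-" else config_hash(config))
  if (!reproducible) hdr <- c(hdr, paste0("# written=", format(Sys.time())))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_prov <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run configuration with the published default thresholds
#'
#' Defaults: PTC distance strictly > 50 nt; down-regulation at
#' log2 fold-change <= -1 with p <= 0.1; 3' UTR classes at 350 / 1500 nt;
#' gene-ontology input lists at log2 fold-change <= -0.4; restoration at
#' any positive log2 fold-change.
#'
#' @param ... Overrides for any field.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    ptc_min_distance = 50,
    fc_threshold = 1,
    p_threshold = 0.1,
    go_fc_threshold = 0.4,
    utr3_short_max = 350,
    utr3_long_min = 1500,
    restore_threshold = 0,
    uorf_frame_match = FALSE,
    min_orf_len = 3,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Annotate NMD features from a GTF and genome FASTA
#'
#' Reads the annotation, applies the protein-coding biotype filter, runs
#' [annotate_all()] and writes the feature TSV.
#'
#' @param gtf,fasta Input paths.
#' @param out Output TSV path.
#' @param config A [run_config()].
#' @return The feature data.frame, invisibly; side effect: `out` written.
#' @export
cmd_annotate <- function(gtf, fasta, out, config = run_config()) {
  genome <- read_genome_fasta(fasta)
  ts <- read_gtf(gtf)
  ts <- filter_biotypes(ts)
  removed <- attr(ts, "removed")
  if (length(removed))
    message("biotype filter removed: ",
            paste(names(removed), removed, sep = "=", collapse = ", "))
  feats <- annotate_all(
    ts, genome,
    min_len = config$min_orf_len,
    uorf_frame_match = config$uorf_frame_match,
    ptc_min_distance = config$ptc_min_distance,
    utr3_short_max = config$utr3_short_max,
    utr3_long_min = config$utr3_long_min)
  skipped <- attr(feats, "skipped")
  if (nrow(skipped)) message(nrow(skipped), " transcript(s) without a complete ORF skipped")
  write_table_prov(feats, out, seed = config$seed, config = unclass(config))
  invisible(feats)
}

#' Enrichment, 3' UTR fold-change, and restoration statistics
#'
#' Filters the expression table, classifies the daf-2-like contrast,
#' runs the chi-squared fraction tests (PTC, uORF), the rank-sum tests by
#' 3' UTR class, and the restoration analysis, and writes a JSON summary
#' plus TSVs.
#'
#' @param features_tsv Feature TSV from [cmd_annotate()].
#' @param expression_tsv Expression TSV (see [gen_expression()] for the
#'   column contract).
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param contrast_down,contrast_restore Contrast names.
#' @return List of results, invisibly.
#' @export
cmd_enrich <- function(features_tsv, expression_tsv, out_dir,
                       config = run_config(),
                       contrast_down = "daf2_vs_WT",
                       contrast_restore = "smg2daf2_vs_daf2") {
  feats <- read_table_prov(features_tsv)
  expr <- filter_expression(read_table_prov(expression_tsv))
  de <- classify_de(expr, contrast_down, config$fc_threshold, config$p_threshold)
  enr_ptc <- feature_fraction_test(de, feats, "ptc")
  enr_uorf <- feature_fraction_test(de, feats, "uorf")
  utr3 <- utr3_foldchange_test(expr, feats, contrast_down)
  rest <- restoration_analysis(
    expr, contrast_down, contrast_restore,
    fc_threshold = config$fc_threshold, p_threshold = config$p_threshold,
    restore_threshold = config$restore_threshold, features = feats)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  enr_tbl <- data.frame(
    feature = c("ptc", "uorf"),
    contrast = contrast_down,
    chi2 = c(enr_ptc$chi2, enr_uorf$chi2),
    p = c(enr_ptc$p, enr_uorf$p),
    fraction_down = c(enr_ptc$fractions[1], enr_uorf$fractions[1]),
    fraction_not_down = c(enr_ptc$fractions[2], enr_uorf$fractions[2]))
  write_table_prov(enr_tbl, file.path(out_dir, "enrichment.tsv"),
                   seed = config$seed, config = unclass(config))
  write_table_prov(as.data.frame(rest), file.path(out_dir, "restoration.tsv"),
                   seed = config$seed, config = unclass(config))
  summary <- list(
    provenance = list(seed = config$seed,
                      config = config_hash(unclass(config)),
                      thresholds = unclass(config)),
    chi2 = list(
      ptc = list(chi2 = enr_ptc$chi2, p = enr_ptc$p,
                 fractions = as.list(enr_ptc$fractions),
                 table = as.vector(enr_ptc$table)),
      uorf = list(chi2 = enr_uorf$chi2, p = enr_uorf$p,
                  fractions = as.list(enr_uorf$fractions),
                  table = as.vector(enr_uorf$table))),
    wilcoxon = list(medians = as.list(utr3$medians), n = as.list(utr3$n),
                    tests = utr3$tests),
    restoration = attr(rest, "summary")
  )
  jsonlite::write_json(summary, file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(enrichment = list(ptc = enr_ptc, uorf = enr_uorf),
                 utr3 = utr3, restoration = rest, summary = summary))
}

#' Fit half-lives for every gene x genotype in a decay CSV
#'
#' @param decay_csv Decay time-course CSV (gene, genotype, time,
#'   replicate, abundance).
#' @param out Output TSV of half-life estimates.
#' @param config A [run_config()].
#' @return data.frame of estimates, invisibly.
#' @export
cmd_halflife <- function(decay_csv, out, config = run_config()) {
  tc <- read_table_prov(decay_csv, sep = ",")
  groups <- split(tc, list(tc$gene, tc$genotype), drop = TRUE)
  est <- do.call(rbind, lapply(groups, function(g) {
    e <- fit_decay(g)
    data.frame(gene = e$gene, genotype = e$genotype, k = e$k,
               t_half = e$t_half, se_k = e$se_k, r2 = e$r2,
               no_decay = e$no_decay)
  }))
  rownames(est) <- NULL
  write_table_prov(est, out, seed = config$seed, config = unclass(config))
  invisible(est)
}

#' Lifespan summaries and pairwise log-rank tests
#'
#' @param survival_csv Survival CSV (animal_id, group, day, event).
#' @param out_dir Output directory (summary and pairwise TSVs).
#' @param config A [run_config()].
#' @param reference Reference group for percent change (default: first).
#' @return List with `summary` and `pairwise` data.frames, invisibly.
#' @export
cmd_survive <- function(survival_csv, out_dir, config = run_config(),
                        reference = NULL) {
  rec <- read_table_prov(survival_csv, sep = ",")
  groups <- unique(rec$group)
  if (is.null(reference)) reference <- groups[1L]
  summ <- do.call(rbind, lapply(groups, function(g) {
    s <- summarize_lifespan(rec, g, reference = reference)
    data.frame(group = g, mean_lifespan = s$mean_lifespan, sem = s$sem,
               n_deaths = s$n_deaths, n_censored = s$n_censored,
               pct_change_vs_ref = s$pct_change)
  }))
  pairs <- utils::combn(groups, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    lr <- logrank_test(rec, pairs[1L, j], pairs[2L, j])
    data.frame(groupA = pairs[1L, j], groupB = pairs[2L, j],
               chi2 = lr$chi2, df = lr$df, p = lr$p)
  }))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_prov(summ, file.path(out_dir, "lifespan_summary.tsv"),
                   seed = config$seed, config = unclass(config))
  write_table_prov(pw, file.path(out_dir, "logrank_pairwise.tsv"),
                   seed = config$seed, config = unclass(config))
  invisible(list(summary = summ, pairwise = pw))
}

#' Write a full synthetic input set
#'
#' @param seed Generator seed.
#' @param out_dir Output directory.
#' @param n_transcripts Number of protein-coding transcripts.
#' @return The [synthetic_spec()] used, invisibly.
#' @export
cmd_simulate <- function(seed, out_dir, n_transcripts = 300L) {
  spec <- synthetic_spec(seed = as.integer(seed),
                         n_transcripts = as.integer(n_transcripts),
                         n_nmd_targets = max(10L, round(n_transcripts / 5)))
  gen <- gen_genome_and_transcripts(spec, dir = out_dir)
  gen_expression(spec, gen$truth, dir = out_dir)
  gen_decay(spec, dir = out_dir)
  gen_survival(spec, dir = out_dir)
  invisible(spec)
}

#' One-command end-to-end demo on synthetic data
#'
#' Generates a synthetic genome/annotation/expression/decay/survival set,
#' runs annotation, enrichment, half-life fitting and survival analysis,
#' checks feature calls against the generator truth, and writes a
#' `demo_summary.json`. Byte-reproducible for a fixed seed.
#'
#' @param seed Seed for the synthetic spec.
#' @param out_dir Output directory.
#' @param n_transcripts Scale of the synthetic genome.
#' @return List with paths and the truth-recovery accuracy, invisibly.
#' @export
cmd_demo <- function(seed = 1L, out_dir, n_transcripts = 300L) {
  config <- run_config(seed = as.integer(seed))
  cmd_simulate(seed, out_dir, n_transcripts = n_transcripts)
  feats_tsv <- file.path(out_dir, "features.tsv")
  feats <- cmd_annotate(file.path(out_dir, "annotation.gtf"),
                        file.path(out_dir, "genome.fa"),
                        feats_tsv, config = config)
  truth <- read_table_prov(file.path(out_dir, "truth.tsv"))
  m <- match(truth$transcript_id, feats$transcript_id)
  acc <- mean(!is.na(m) &
                feats$has_ptc[m] == truth$has_ptc &
                feats$has_uorf[m] == truth$has_uorf &
                feats$utr3_category[m] == truth$utr3_category)
  enrich <- cmd_enrich(feats_tsv, file.path(out_dir, "expression.tsv"),
                       file.path(out_dir, "stats"), config = config)
  est <- cmd_halflife(file.path(out_dir, "decay.csv"),
                      file.path(out_dir, "halflife.tsv"), config = config)
  surv <- cmd_survive(file.path(out_dir, "survival.csv"),
                      file.path(out_dir, "stats"), config = config)
  summary <- list(
    provenance = list(seed = as.integer(seed),
                      config = config_hash(unclass(config))),
    truth_recovery_accuracy = acc,
    n_transcripts = nrow(feats),
    enrichment_p = list(ptc = enrich$summary$chi2$ptc$p,
                        uorf = enrich$summary$chi2$uorf$p),
    restoration = enrich$summary$restoration[c("n_down", "n_restored",
                                               "fraction_restored")],
    half_lives = est[c("gene", "genotype", "t_half")],
    logrank = surv$pairwise
  )
  jsonlite::write_json(summary, file.path(out_dir, "demo_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, accuracy = acc, summary = summary))
}

# --- command-line dispatcher ------------------------------------------------

user_error <- function(...) {
  stop(structure(class = c("nmd_user_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

parse_flags <- function(args) {
  flags <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        flags[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        flags[[key]] <- TRUE; i <- i + 1L
      }
    } else {
      pos <- c(pos, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

need_flag <- function(p, key) {
  v <- p$flags[[key]]
  if (is.null(v)) user_error("missing required flag --", key)
  v
}

#' Command-line entry point
#'
#' Subcommands: `annotate --gtf F --fasta F --out F`,
#' `enrich --features F --expression F --out-dir D`,
#' `halflife --decay F --out F`, `survive --survival F --out-dir D`,
#' `simulate --seed N --out-dir D`, `demo --seed N --out-dir D`.
#' Threshold flags (`--fc-threshold`, `--p-threshold`, `--ptc-distance`,
#' `--restore-threshold`, `--uorf-frame-match`) override the defaults.
#' Exit codes: 0 ok, 1 user error, 2 internal error.
#'
#' @param args Character vector of arguments (default: the process
#'   command line).
#' @return Integer exit status, invisibly.
#' @export
nmd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) user_error(
      "usage: nmdpipe <annotate|enrich|halflife|survive|simulate|demo> [flags]")
    cmd <- args[1L]
    p <- parse_flags(args[-1L])
    cfg_over <- list()
    if (!is.null(p$flags[["fc-threshold"]]))
      cfg_over$fc_threshold <- as.numeric(p$flags[["fc-threshold"]])
    if (!is.null(p$flags[["p-threshold"]]))
      cfg_over$p_threshold <- as.numeric(p$flags[["p-threshold"]])
    if (!is.null(p$flags[["ptc-distance"]]))
      cfg_over$ptc_min_distance <- as.numeric(p$flags[["ptc-distance"]])
    if (!is.null(p$flags[["restore-threshold"]]))
      cfg_over$restore_threshold <- as.numeric(p$flags[["restore-threshold"]])
    if (isTRUE(p$flags[["uorf-frame-match"]]))
      cfg_over$uorf_frame_match <- TRUE
    if (!is.null(p$flags[["seed"]]))
      cfg_over$seed <- as.integer(p$flags[["seed"]])
    config <- do.call(run_config, cfg_over)
    check_file <- function(f) {
      if (!file.exists(f)) user_error("input file not found: ", f)
      f
    }
    switch(cmd,
      annotate = cmd_annotate(check_file(need_flag(p, "gtf")),
                              check_file(need_flag(p, "fasta")),
                              need_flag(p, "out"), config = config),
      enrich = cmd_enrich(check_file(need_flag(p, "features")),
                          check_file(need_flag(p, "expression")),
                          need_flag(p, "out-dir"), config = config),
      halflife = cmd_halflife(check_file(need_flag(p, "decay")),
                              need_flag(p, "out"), config = config),
      survive = cmd_survive(check_file(need_flag(p, "survival")),
                            need_flag(p, "out-dir"), config = config),
      simulate = cmd_simulate(config$seed, need_flag(p, "out-dir")),
      demo = cmd_demo(config$seed, need_flag(p, "out-dir")),
      user_error("unknown subcommand: ", cmd))
    0L
  },
  nmd_user_error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  },
  error = function(e) {
    message("internal error: ", conditionMessage(e)); 2L
  })
  invisible(status)
}
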