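# mRNA decay kinetics: comparative Ct quantification, first-order decay
# fitting of transcription-shutoff (DRB chase) time courses, genotype
# comparison by two-way ANOVA, and reporter-intensity normalization.
#
# A decay time course is a data.frame with columns: gene, genotype, time
# (minutes after transcription shutoff), replicate, abundance (relative
# units, normalized to the reference RNA and to that replicate's t = 0).

#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' dCt = Ct(target) - Ct(reference) per sample; ddCt = dCt(sample) -
#' dCt(calibrator); relative level = 2^-ddCt.
#'
#' @param m List or data.frame with numeric `ct_target`, `ct_reference`
#'   (the sample; vectors allowed).
#' @param calibrator Same shape, the calibrator sample.
#' @return Relative abundance (1 for the calibrator itself).
#' @export
ddct_relative_level <- function(m, calibrator) {
  ct <- c(m$ct_target, m$ct_reference, calibrator$ct_target, calibrator$ct_reference)
  if (any(!is.finite(ct))) stop("non-finite Ct value")
  dct_sample <- m$ct_target - m$ct_reference
  dct_cal <- calibrator$ct_target - calibrator$ct_reference
  2^(-(dct_sample - dct_cal))
}

#' Fit first-order decay and estimate the mRNA half-life
#'
#' Least-squares fit of `ln(abundance) = -k * t`. Because abundance is
#' normalized to 1 at t = 0, the intercept is fixed at 0 by default; a
#' free-intercept variant is available as a robustness check. Zero or
#' negative abundances (possible after background subtraction) are
#' replaced by half the smallest positive observed value before the log
#' transform (`zero_policy = "half_min"`) or dropped.
#'
#' @param tc Decay time course data.frame (see module header), one
#'   gene x genotype.
#' @param intercept Fit a free intercept instead of forcing ln(1) = 0.
#' @param zero_policy `"half_min"` or `"drop"`.
#' @return List of class `halflife_estimate`: `gene`, `genotype`, `k`
#'   (per minute), `t_half` (minutes, `NA` when no decay), `se_k`, `r2`,
#'   `no_decay`, `n_nonpositive` (count of adjusted abundances).
#' @export
fit_decay <- function(tc, intercept = FALSE, zero_policy = c("half_min", "drop")) {
  zero_policy <- match.arg(zero_policy)
  if (length(unique(tc$time)) < 3L) stop("need >= 3 timepoints")
  ab <- tc$abundance; tt <- tc$time
  nonpos <- ab <= 0
  if (any(nonpos)) {
    if (!any(ab > 0)) stop("no positive abundances")
    if (zero_policy == "half_min") {
      ab[nonpos] <- min(ab[ab > 0]) / 2
    } else {
      ab <- ab[!nonpos]; tt <- tt[!nonpos]
    }
  }
  y <- log(ab)
  fit <- if (intercept) stats::lm(y ~ tt) else stats::lm(y ~ 0 + tt)
  # noiseless series are a designed use case; muffle the perfect-fit warning
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope_row <- if (intercept) 2L else 1L
  k <- -unname(stats::coef(fit)[slope_row])
  se_k <- sm$coefficients[slope_row, "Std. Error"]
  no_decay <- k <= 0
  structure(
    list(gene = tc$gene[1L], genotype = tc$genotype[1L],
         k = k, t_half = if (no_decay) NA_real_ else log(2) / k,
         se_k = se_k, r2 = sm$r.squared, no_decay = no_decay,
         n_nonpositive = sum(nonpos)),
    class = "halflife_estimate"
  )
}

#' @export
print.halflife_estimate <- function(x, ...) {
  cat(sprintf("<halflife_estimate> %s / %s: ", x$gene, x$genotype))
  if (x$no_decay) cat("no decay (k <= 0)\n")
  else cat(sprintf("k = %.5g /min, t1/2 = %.4g min (se_k %.3g, R2 %.3f)\n",
                   x$k, x$t_half, x$se_k, x$r2))
  invisible(x)
}

#' Compare decay time courses between genotypes by two-way ANOVA
#'
#' Fixed-effects ANOVA of abundance on genotype x time (both treated as
#' factors) over a balanced design; with balance, type I and type II sums
#' of squares coincide.
#'
#' @param tcA,tcB Decay time courses with distinct `genotype` labels,
#'   shared timepoints, and >= 2 replicates per genotype x time cell.
#' @return data.frame with rows genotype / time / interaction: `df`,
#'   `sum_sq`, `F`, `p`.
#' @export
compare_decay <- function(tcA, tcB) {
  if (identical(unique(tcA$genotype), unique(tcB$genotype)))
    stop("genotype labels must differ between the two time courses")
  d <- rbind(tcA[c("genotype", "time", "abundance")],
             tcB[c("genotype", "time", "abundance")])
  d$genotype <- factor(d$genotype)
  d$time_f <- factor(d$time)
  cells <- table(d$genotype, d$time_f)
  if (any(cells == 0) || any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1L, ]
    stop(sprintf("cell genotype=%s, time=%s has < 2 replicates",
                 rownames(cells)[bad[1L]], colnames(cells)[bad[2L]]))
  }
  if (length(unique(as.vector(cells))) > 1L) {
    bad <- which(cells == min(cells), arr.ind = TRUE)[1L, ]
    stop(sprintf("unbalanced design at cell genotype=%s, time=%s",
                 rownames(cells)[bad[1L]], colnames(cells)[bad[2L]]))
  }
  a <- stats::anova(stats::lm(abundance ~ genotype * time_f, data = d))
  data.frame(
    effect = c("genotype", "time", "interaction"),
    df = a$Df[1:3],
    sum_sq = a$`Sum Sq`[1:3],
    F = a$`F value`[1:3],
    p = a$`Pr(>F)`[1:3],
    stringsAsFactors = FALSE
  )
}

#' Background-corrected NMD reporter intensity ratio
#'
#' Mean background-subtracted intensity of the PTC reporter divided by
#' that of the wild-type reporter; backgrounds come from age- and
#' genotype-matched non-transgenic animals.
#'
#' @param intensity_ptc,intensity_wt Per-animal intensities.
#' @param auto_ptc,auto_wt Autofluorescence backgrounds (scalars, matched
#'   controls).
#' @return List `ratio`, `per_animal` (PTC animals, normalized to the WT
#'   mean), `sem_ptc`, `sem_wt`. Negative numerators (reporter dimmer
#'   than background) pass through with a warning; a non-positive
#'   denominator is an error.
#' @export
reporter_ratio <- function(intensity_ptc, intensity_wt, auto_ptc, auto_wt) {
  num_i <- intensity_ptc - auto_ptc
  den_i <- intensity_wt - auto_wt
  den <- mean(den_i)
  if (den <= 0) stop("wild-type reporter not above background")
  num <- mean(num_i)
  if (num < 0) warning("PTC reporter dimmer than background; negative ratio")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(ratio = num / den, per_animal = num_i / den,
       sem_ptc = sem(num_i), sem_wt = sem(den_i))
}
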