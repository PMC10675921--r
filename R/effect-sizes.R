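# Effect sizes, RT-qPCR processing rules, relative-fraction fold changes,
# and the functional-exon extrapolation arithmetic.

#' Two-group summary statistics
#'
#' Either supply raw vectors `x`/`y` or the six summary numbers directly.
#'
#' @param x,y numeric vectors (group 1 and 2).
#' @param n1,n2,mean1,mean2,sd1,sd2 summary statistics (used when `x`/`y`
#'   are `NULL`).
#' @return list of class `two_group_summary`.
#' @export
two_group_summary <- function(x = NULL, y = NULL, n1 = NULL, n2 = NULL,
                              mean1 = NULL, mean2 = NULL,
                              sd1 = NULL, sd2 = NULL) {
  if (!is.null(x)) {
    n1 <- length(x); mean1 <- mean(x); sd1 <- stats::sd(x)
  }
  if (!is.null(y)) {
    n2 <- length(y); mean2 <- mean(y); sd2 <- stats::sd(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  structure(list(n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
                 sd1 = sd1, sd2 = sd2), class = "two_group_summary")
}

#' Cohen's d (pooled standard deviation)
#'
#' `d = (mean2 - mean1) / sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))`.
#' A zero pooled SD with equal means gives 0; with unequal means it is an
#' error.
#'
#' @param s a [two_group_summary()].
#' @return Cohen's d.
#' @export
cohens_d <- function(s) {
  stopifnot(inherits(s, "two_group_summary"))
  pooled <- sqrt(((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) /
                   (s$n1 + s$n2 - 2))
  delta <- s$mean2 - s$mean1
  if (pooled == 0) {
    if (delta == 0) return(0)
    stopf("zero pooled SD with unequal means: d undefined")
  }
  delta / pooled
}

#' Hedges' g (small-sample corrected Cohen's d)
#'
#' `g = d * (1 - 3 / (4 (n1 + n2) - 9))`.
#'
#' @param s a [two_group_summary()].
#' @return Hedges' g.
#' @export
hedges_g <- function(s) {
  stopifnot(inherits(s, "two_group_summary"))
  if (4 * (s$n1 + s$n2) - 9 <= 0) stopf("sample sizes too small for g")
  cohens_d(s) * (1 - 3 / (4 * (s$n1 + s$n2) - 9))
}

#' Clean an RT-qPCR technical triplet
#'
#' Missing Ct values are imputed at `max_cycles` (no amplification within
#' the run). If exactly one replicate differs by more than 2 Ct from each of
#' the other two while those two agree within 2 Ct, it is excluded;
#' otherwise all three are kept.
#'
#' @param ct numeric vector of 3 Ct values (`NA` marks missing); a length-2
#'   vector from a previous cleaning pass is returned unchanged, making the
#'   operation idempotent.
#' @param max_cycles cycle ceiling used for imputation; default 40.
#' @return retained Ct values (length 2 or 3).
#' @export
clean_qpcr <- function(ct, max_cycles = 40) {
  if (length(ct) == 2 && !anyNA(ct)) return(unname(ct))
  if (length(ct) != 3) stopf("expected exactly 3 technical replicates")
  ct[is.na(ct)] <- max_cycles
  for (i in 1:3) {
    others <- ct[-i]
    if (all(abs(ct[i] - others) > 2) && abs(diff(others)) <= 2)
      return(unname(others))
  }
  unname(ct)
}

#' qPCR log2 fold change with an all-cross-pairs paired t test
#'
#' Per replicate, log2 expression is `-(Ct - Ct_reference)` when a
#' reference-gene Ct is supplied, else `-Ct`. The fold change is
#' `2^(mean treated - mean control)`; the p-value comes from a paired t test
#' over all treated x control cross-pairs (up to 6 x 6 = 36). Fold changes
#' limited by the `max_cycles` imputation floor are flagged.
#'
#' @param treated,control numeric vectors of cleaned Ct values (up to 6
#'   each: 2 biological x 3 technical replicates).
#' @param reference_treated,reference_control optional reference-gene Ct
#'   values (scalar or vector; means are used).
#' @param max_cycles imputation ceiling used to flag floor-limited results.
#' @return list: `log2_fc`, `fold_change`, `t`, `df`, `p`,
#'   `floor_limited`.
#' @export
qpcr_log2fc <- function(treated, control, reference_treated = NULL,
                        reference_control = NULL, max_cycles = 40) {
  if (length(treated) < 2 || length(control) < 2)
    stopf("need at least 2 Ct values per arm")
  et <- -(treated - if (is.null(reference_treated)) 0
          else mean(reference_treated))
  ec <- -(control - if (is.null(reference_control)) 0
          else mean(reference_control))
  d <- as.vector(outer(et, ec, `-`))
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    p <- if (abs(m) < .Machine$double.eps) 1 else .Machine$double.xmin
    t <- if (abs(m) < .Machine$double.eps) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), n - 1)
  }
  list(log2_fc = m, fold_change = 2^m, t = t, df = n - 1, p = p,
       floor_limited = any(treated >= max_cycles) ||
         any(control >= max_cycles))
}

#' Fold change of a novel transcript relative to the annotated isoform
#'
#' When the annotated isoform goes down while the novel one goes up, the
#' novel fraction changes by the product of the two folds; when both go up,
#' by their ratio. Reported values are rounded half-up to one decimal
#' (`digits = NULL` for the raw value).
#'
#' @param fc_novel fold change of the novel transcript (> 0).
#' @param fc_annotated fold change magnitude of the annotated isoform (> 0).
#' @param annotated_direction `"down"` or `"up"`.
#' @param digits decimals for reporting; default 1.
#' @return relative fraction fold change.
#' @export
relative_fraction_change <- function(fc_novel, fc_annotated,
                                     annotated_direction = c("down", "up"),
                                     digits = 1) {
  annotated_direction <- match.arg(annotated_direction)
  if (fc_novel <= 0 || fc_annotated <= 0) stopf("folds must be positive")
  out <- if (annotated_direction == "down") fc_novel * fc_annotated
         else fc_novel / fc_annotated
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Extrapolated count of functional unannotated exons
#'
#' `total_exons x frac_phenotypic x frac_class`, with roundings to the
#' nearest hundred and thousand for reporting.
#'
#' @param total_exons total candidate exon count.
#' @param frac_phenotypic fraction of candidate exons harboring phenotypic
#'   calls.
#' @param frac_class fraction of characterized candidates in the class of
#'   interest (e.g. spliced transcripts).
#' @return list: `raw`, `nearest_hundred`, `nearest_thousand`.
#' @export
extrapolate_exon_count <- function(total_exons, frac_phenotypic,
                                   frac_class) {
  stopifnot(frac_phenotypic >= 0, frac_phenotypic <= 1,
            frac_class >= 0, frac_class <= 1)
  raw <- total_exons * frac_phenotypic * frac_class
  list(raw = raw,
       nearest_hundred = round_half_up(raw / 100, 0) * 100,
       nearest_thousand = round_half_up(raw / 1000, 0) * 1000)
}
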