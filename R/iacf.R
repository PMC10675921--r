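# Single-site fitness calls (IACFs): insertions affecting cellular fitness.
#
# Per unique insertion site, normalized depths from 3 control and 3 treated
# biological replicates are log10-transformed with a fixed floor for zeros,
# compared by a paired t test over all 9 treated-control replicate pairs,
# and selected by Benjamini-Hochberg FDR within the assay system.

#' IACF calling parameters
#'
#' @param log_floor log10 value assigned to zero-depth sites; default -5
#'   (below any observable nonzero CPM at realistic library sizes).
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff; default 0.25.
#' @return list of class `iacf_params`.
#' @export
iacf_params <- function(log_floor = -5, fdr_threshold = 0.25) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  structure(list(log_floor = log_floor, fdr_threshold = fdr_threshold),
            class = "iacf_params")
}

#' Floored log10 transform
#'
#' Positive depths map to `log10(v)`; zeros map to `floor`.
#'
#' @param x non-negative numeric vector/matrix of normalized depths.
#' @param floor value assigned to zeros; default -5.
#' @return transformed values, same shape as `x`.
#' @export
log10_floor <- function(x, floor = -5) {
  if (any(x < 0)) stopf("negative depth passed to log10_floor")
  out <- x
  out[x > 0] <- log10(x[x > 0])
  out[x == 0] <- floor
  out
}

#' Paired t test over all replicate cross-pairs
#'
#' With unpaired replicate labels there is no natural 1-1 pairing between
#' control and treated replicates, so the paired sample is formed from all
#' `length(treated) x length(control)` differences (9 for 3 vs 3), and a
#' standard one-sample t test is applied to the differences (df = n - 1 = 8).
#' Degenerate cases: all differences zero gives t = 0, p = 1; zero variance
#' with nonzero mean gives the smallest representable positive p.
#'
#' @param control,treated numeric vectors of (log-transformed) depths; at
#'   least 3 values each.
#' @return list with `t`, `df`, `p`, `mean_diff` (treated minus control).
#' @export
paired_t_all_pairs <- function(control, treated) {
  if (length(control) < 3 || length(treated) < 3)
    stopf("need at least 3 replicates per arm")
  d <- as.vector(outer(treated, control, `-`))
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    if (abs(m) < .Machine$double.eps)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    return(list(t = sign(m) * Inf, df = n - 1, p = .Machine$double.xmin,
                mean_diff = m))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), mean_diff = m)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values outside [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call insertions affecting cellular fitness
#'
#' The testing universe is every site with a nonzero raw count in at least
#' one of the six samples of the system. Per site: floored log10 transform of
#' the normalized depths, paired t over all 9 replicate cross-pairs, BH
#' adjustment across the universe, retention at `q <= fdr_threshold`.
#' Direction is the sign of the mean log difference (treated - control).
#'
#' Replicate labels carry no natural 1-1 pairing, so the default forms all
#' 9 cross-pairs (`pairing = "cross"`, df = 8). Note that the 9 differences
#' share only 6 underlying values, which understates the standard error of
#' the mean difference and makes the cross-pair test anti-conservative;
#' `pairing = "matched"` (replicate i vs replicate i, df = 2) is the
#' variant with nominal type-I behavior and is used wherever calibrated
#' error control matters.
#'
#' @param matrix a normalized `insertion_matrix` (see [normalize_depth()]).
#' @param control_samples,treated_samples character vectors of exactly 3
#'   sample names each.
#' @param params an [iacf_params()] object.
#' @param pairing `"cross"` (all 9 pairs, default) or `"matched"`
#'   (replicate-index pairs).
#' @param keep_all if `TRUE`, return all tested sites, not only calls.
#' @return data.frame: `chrom`, `pos`, `strand`, `mean_log_diff`,
#'   `direction` (`"enriched"`/`"depleted"`), `p`, `q`, `called`.
#' @export
call_iacfs <- function(matrix, control_samples, treated_samples,
                       params = iacf_params(),
                       pairing = c("cross", "matched"),
                       keep_all = FALSE) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(matrix, "insertion_matrix"))
  if (is.null(matrix$norm)) matrix <- normalize_depth(matrix)
  if (length(control_samples) != 3 || length(treated_samples) != 3)
    stopf("exactly 3 replicates per arm are required")
  miss <- setdiff(c(control_samples, treated_samples),
                  colnames(matrix$counts))
  if (length(miss)) stopf("unknown sample(s): %s", paste(miss, collapse = ", "))

  raw <- matrix$counts[, c(control_samples, treated_samples), drop = FALSE]
  universe <- rowSums(raw) > 0
  Lc <- log10_floor(matrix$norm[universe, control_samples, drop = FALSE],
                    params$log_floor)
  Lt <- log10_floor(matrix$norm[universe, treated_samples, drop = FALSE],
                    params$log_floor)

  if (pairing == "cross") {
    # Closed-form moments of the 9 cross differences t_j - c_i:
    #   sum(d)   = 3*sum(Lt) - 3*sum(Lc)
    #   sum(d^2) = 3*sum(Lt^2) + 3*sum(Lc^2) - 2*sum(Lt)*sum(Lc)
    st <- rowSums(Lt); sc <- rowSums(Lc)
    st2 <- rowSums(Lt^2); sc2 <- rowSums(Lc^2)
    n <- 9
    sum_d <- 3 * st - 3 * sc
    sum_d2 <- 3 * st2 + 3 * sc2 - 2 * st * sc
    m <- sum_d / n
    var_d <- pmax(0, (sum_d2 - sum_d^2 / n) / (n - 1))
  } else {
    D <- Lt - Lc
    n <- ncol(D)
    m <- rowMeans(D)
    var_d <- pmax(0, (rowSums(D^2) - n * m^2) / (n - 1))
  }
  s <- sqrt(var_d)

  # guard against catastrophic cancellation in the closed-form variance
  zero_var <- s <= 1e-9 * pmax(1, abs(m))
  tstat <- ifelse(!zero_var, m / (s / sqrt(n)), 0)
  p <- ifelse(!zero_var, 2 * stats::pt(-abs(tstat), n - 1),
              ifelse(abs(m) < 1e-9, 1, .Machine$double.xmin))
  q <- bh_adjust(p)

  out <- data.frame(matrix$sites[universe, , drop = FALSE],
                    mean_log_diff = m,
                    direction = ifelse(m > 0, "enriched", "depleted"),
                    p = p, q = q,
                    called = q <= params$fdr_threshold & m != 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_all) out else out[out$called, , drop = FALSE]
}
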