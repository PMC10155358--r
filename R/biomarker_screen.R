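#' Region x sample mean-signal matrix
#'
#' Entry (r, s) is the mean of the chosen signal over the region's callable
#' CpGs in sample s, `NA` when the sample covers fewer than `min_sites`
#' region CpGs.  Regions with no callable CpG in any sample are dropped with
#' a warning.
#'
#' @param regions data.frame with chrom, start, end (0-based half-open);
#'   rownames (or a `region` column) become region ids.
#' @param pm A `paired_methylome`.
#' @param signal `"5mC"`, `"5hmC"` or `"BS"`.
#' @param min_sites Minimum callable CpGs per sample entry (default 1).
#' @return Numeric matrix, regions x samples.
#' @export
region_sample_means <- function(regions, pm, signal = c("5mC", "5hmC", "BS"),
                                min_sites = 1L) {
  signal <- match.arg(signal)
  X <- signal_matrix(pm, signal)
  ids <- if (!is.null(regions$region)) regions$region else
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  out <- matrix(NA_real_, nrow(regions), ncol(X),
                dimnames = list(ids, colnames(X)))
  for (i in seq_len(nrow(regions))) {
    rows <- which(pm$map$chrom == regions$chrom[i] &
                    pm$map$pos >= regions$start[i] &
                    pm$map$pos < regions$end[i])
    if (length(rows) == 0L) next
    sub <- X[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    mu[n_ok < min_sites] <- NA_real_
    out[i, ] <- mu
  }
  empty <- rowSums(!is.na(out)) == 0L
  if (any(empty)) {
    warning(sum(empty), " region(s) with no callable CpG in any sample dropped")
    out <- out[!empty, , drop = FALSE]
  }
  out
}

#' Rank-based AUC of a univariate marker
#'
#' Mann-Whitney estimator with mid-rank tie handling: the probability that a
#' random case sample's value exceeds a random control's (ties count 1/2).
#' Identical to the normalised U statistic of [test_region()].
#'
#' @param values Per-sample marker values (NA dropped together with their
#'   labels).
#' @param is_case Logical vector, TRUE for case samples.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 1
auc <- function(values, is_case) {
  stopifnot(length(values) == length(is_case))
  ok <- !is.na(values) & !is.na(is_case)
  values <- values[ok]; is_case <- is_case[ok]
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Screen DMRs as univariate AUC biomarkers
#'
#' Evaluates every DMR's per-sample region mean on the chosen signal as a
#' univariate classifier of the contrast, flagging markers with
#' AUC > `auc_cutoff` that are also significant DMRs.  Regions are evaluated
#' only when at least `min_frac_samples` of the contrast samples have a
#' value.
#'
#' @param dmrs A `dmr_set` (or data.frame with chrom/start/end and
#'   optionally `significant`).
#' @param pm A `paired_methylome`.
#' @param contrast A [contrast_design()]; defaults to the cohort labels.
#' @param signal Signal to evaluate; defaults to the DMR set's own mark.
#' @param auc_cutoff Screen threshold (default 0.8).
#' @param min_frac_samples Minimum fraction of samples with a value.
#' @return A `biomarker_screen` data.frame sorted by AUC (descending):
#'   region, signal, n_cpgs, mean_diff, q, auc, passes_screen.
#' @export
screen_biomarkers <- function(dmrs, pm, contrast = NULL, signal = NULL,
                              auc_cutoff = 0.8, min_frac_samples = 0.8) {
  if (is.null(signal)) signal <- attr(dmrs, "mark")
  if (is.null(signal)) stop("signal must be given when dmrs carries no mark")
  if (is.null(contrast)) {
    if (is.null(pm$groups)) stop("no contrast given and cohort has no groups")
    contrast <- contrast_design("case_vs_control",
                                names(pm$groups)[pm$groups == "case"],
                                names(pm$groups)[pm$groups == "control"])
  }
  d <- as.data.frame(dmrs)
  if (nrow(d) == 0L) {
    out <- data.frame(region = character(), signal = character(),
                      n_cpgs = integer(), mean_diff = numeric(),
                      q = numeric(), auc = numeric(),
                      passes_screen = logical())
    class(out) <- c("biomarker_screen", "data.frame")
    return(out)
  }
  mm <- region_sample_means(d, pm, signal)
  samples <- c(contrast$case, contrast$control)
  is_case <- c(rep(TRUE, length(contrast$case)),
               rep(FALSE, length(contrast$control)))
  ids <- sprintf("%s:%d-%d", d$chrom, d$start, d$end)
  aucs <- rep(NA_real_, nrow(d))
  for (i in seq_len(nrow(d))) {
    j <- match(ids[i], rownames(mm))
    if (is.na(j)) next
    v <- mm[j, samples]
    if (mean(!is.na(v)) < min_frac_samples) next
    ok <- !is.na(v)
    if (sum(is_case[ok]) == 0L || sum(!is_case[ok]) == 0L) next
    aucs[i] <- auc(v[ok], is_case[ok])
  }
  sig <- if (!is.null(d$significant)) d$significant else rep(TRUE, nrow(d))
  out <- data.frame(region = ids, signal = signal,
                    n_cpgs = if (!is.null(d$n_cpgs)) d$n_cpgs else NA_integer_,
                    mean_diff = if (!is.null(d$mean_diff)) d$mean_diff else
                      NA_real_,
                    q = if (!is.null(d$q)) d$q else NA_real_,
                    auc = aucs,
                    passes_screen = !is.na(aucs) & aucs > auc_cutoff & sig,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$auc), -Inf, out$auc)), ]
  rownames(out) <- NULL
  attr(out, "auc_cutoff") <- auc_cutoff
  attr(out, "contrast") <- contrast$name
  class(out) <- c("biomarker_screen", "data.frame")
  out
}

#' @export
print.biomarker_screen <- function(x, ...) {
  cat(sprintf("biomarker_screen [%s]: %d regions, %d pass (AUC > %.2g)\n",
              if (nrow(x)) x$signal[1] else "-", nrow(x),
              sum(x$passes_screen), attr(x, "auc_cutoff")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Compare the three signals over one region
#'
#' Reports the rank-based AUC and group mean difference of the 5mC (oxBS),
#' 5hmC (subtraction) and combined BS signal over one region - the
#' side-by-side comparison that exposes attenuation of the combined
#' bisulfite signal when 5mC and 5hmC shift in opposite directions.
#'
#' @param region One-row data.frame (chrom, start, end) or a region id
#'   string like `"chr1:100-500"` (0-based half-open).
#' @param pm A `paired_methylome`.
#' @param contrast A [contrast_design()]; defaults to cohort labels.
#' @return data.frame with one row per signal: signal, auc, mean_diff.
#' @export
compare_signals <- function(region, pm, contrast = NULL) {
  if (is.character(region)) {
    m <- regmatches(region, regexec("^(\\S+?):(\\d+)-(\\d+)$", region))[[1]]
    region <- data.frame(chrom = m[2], start = as.integer(m[3]),
                         end = as.integer(m[4]))
  }
  region <- as.data.frame(region)[1, c("chrom", "start", "end")]
  if (is.null(contrast)) {
    if (is.null(pm$groups)) stop("no contrast given and cohort has no groups")
    contrast <- contrast_design("case_vs_control",
                                names(pm$groups)[pm$groups == "case"],
                                names(pm$groups)[pm$groups == "control"])
  }
  samples <- c(contrast$case, contrast$control)
  is_case <- c(rep(TRUE, length(contrast$case)),
               rep(FALSE, length(contrast$control)))
  out <- lapply(c("5mC", "5hmC", "BS"), function(sig) {
    v <- region_sample_means(region, pm, sig)[1, samples]
    ok <- !is.na(v)
    data.frame(signal = sig,
               auc = auc(v[ok], is_case[ok]),
               mean_diff = mean(v[ok & is_case]) - mean(v[ok & !is_case]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between two differential-methylation profiles
#'
#' Correlates two per-region mean-difference vectors over their shared
#' regions - used both for checking whether one contrast's differential
#' profile mimics another's, and for the global anti-correlation between
#' 5mC and 5hmC alterations.
#'
#' @param profile_a,profile_b Named numeric vectors (region id ->
#'   mean difference); at least 3 shared regions required.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `r`, `p`, `n` (shared regions), `method`.
#' @export
profile_correlation <- function(profile_a, profile_b,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(profile_a)) || is.null(names(profile_b)))
    stop("profiles must be named by region")
  shared <- intersect(names(profile_a), names(profile_b))
  shared <- shared[!is.na(profile_a[shared]) & !is.na(profile_b[shared])]
  if (length(shared) < 3L) stop("fewer than 3 shared regions")
  ct <- suppressWarnings(stats::cor.test(profile_a[shared], profile_b[shared],
                                         method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       method = method)
}

#' Per-DMR differential profile
#'
#' Convenience extractor: named mean-difference vector of a `dmr_set` (all
#' tested regions by default), suitable for [profile_correlation()].
#'
#' @param dmrs A `dmr_set`.
#' @param significant_only Restrict to significant DMRs.
#' @return Named numeric vector region id -> mean_diff.
#' @export
differential_profile <- function(dmrs, significant_only = FALSE) {
  d <- as.data.frame(dmrs)
  if (significant_only) d <- d[d$significant, , drop = FALSE]
  stats::setNames(d$mean_diff, sprintf("%s:%d-%d", d$chrom, d$start, d$end))
}
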