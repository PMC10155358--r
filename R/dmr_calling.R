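#' Benjamini-Hochberg step-up adjustment
#'
#' Direct implementation of the step-up procedure: with ordered p-values
#' p_(1) <= ... <= p_(n), the adjusted value for rank i is
#' `min_{j >= i} min(1, n * p_(j) / j)`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return Adjusted q-values in the original order (empty in, empty out).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(pvalues) {
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(pvalues)
  ps <- pvalues[o]
  q <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * ps[i] / i)
    q[i] <- running
  }
  q[order(o)]
}

# mid-rank Mann-Whitney U for the first n1 observations of a pooled sample
.mwu_u <- function(r, n1) sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

#' Two-group region test (Mann-Whitney U on per-sample region means)
#'
#' Two-sided rank-sum test with mid-rank tie handling.  The exact
#' permutation distribution (all `choose(n, n1)` group assignments of the
#' observed values) is used when `n_case + n_control <= exact_max_n`;
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param case_values,control_values Numeric per-sample region means
#'   (NA entries dropped); each group needs >= 2 non-missing values.
#' @param exact_max_n Largest pooled size for exact enumeration (default 12).
#' @return List: `mean_diff` (case - control), `p`, `U`, `n_case`,
#'   `n_control`, `exact`.
#' @export
#' @examples
#' test_region(c(0.9, 0.8, 0.85), c(0.2, 0.1, 0.15))$p  # 0.1 (3v3 separation)
test_region <- function(case_values, control_values, exact_max_n = 12L) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  n1 <- length(x); n0 <- length(y)
  if (n1 < 2L || n0 < 2L) stop("each group needs at least two values")
  n <- n1 + n0
  r <- rank(c(x, y))
  U <- .mwu_u(r, n1)
  mu <- n1 * n0 / 2
  if (n <= exact_max_n) {
    cmb <- utils::combn(n, n1)
    W <- colSums(matrix(r[cmb], nrow = n1))
    Uperm <- W - n1 * (n1 + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    exact <- TRUE
  } else {
    t <- table(r)
    sigma2 <- (n1 * n0 / 12) * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(mean_diff = mean(x) - mean(y), p = p, U = U,
       n_case = n1, n_control = n0, exact = exact)
}

#' Segmentation parameters
#'
#' @param max_gap Maximum distance in bp between neighbouring retained CpGs
#'   within one candidate run.
#' @param min_cpg Minimum CpGs per candidate region.
#' @param min_group_presence Fraction of samples of *each* group in which a
#'   CpG must be callable to be retained.
#' @param split_gain Minimum increase in the larger child's absolute mean
#'   difference (over the parent's) for a binary split to be accepted.
#' @return List of class `seg_params`.
#' @export
seg_params <- function(max_gap = 300L, min_cpg = 5L,
                       min_group_presence = 0.8, split_gain = 0.05) {
  stopifnot(max_gap > 0, min_cpg >= 1, min_group_presence >= 0,
            min_group_presence <= 1, split_gain >= 0)
  structure(list(max_gap = as.integer(max_gap), min_cpg = as.integer(min_cpg),
                 min_group_presence = min_group_presence,
                 split_gain = split_gain),
            class = "seg_params")
}

# recursive binary splitting of one run of per-CpG group differences;
# returns a list of index ranges (relative to the run)
.split_run <- function(d, min_cpg, split_gain) {
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    seg <- d[lo:hi]
    parent <- abs(mean(seg))
    if (n < 2L * min_cpg) return(list(c(lo, hi)))
    cs <- cumsum(seg)
    ks <- min_cpg:(n - min_cpg)
    d1 <- cs[ks] / ks
    d2 <- (cs[n] - cs[ks]) / (n - ks)
    score <- abs(d1 - d2)
    k <- ks[which.max(score)]
    best <- max(abs(d1[k - min_cpg + 1L]), abs(d2[k - min_cpg + 1L]))
    if (best >= parent + split_gain) {
      c(rec(lo, lo + k - 1L), rec(lo + k, hi))
    } else {
      list(c(lo, hi))
    }
  }
  rec(1L, length(d))
}

#' De-novo candidate-region segmentation
#'
#' Retained CpGs are grouped into maximal runs with inter-CpG gaps at most
#' `max_gap`; each run is then recursively split at the breakpoint that
#' maximises the absolute difference of the two children's mean per-CpG
#' group differences, accepting a split only while both children keep at
#' least `min_cpg` CpGs and the larger child's |mean difference| improves on
#' the parent's by at least `split_gain`.  Leaves are the candidate regions.
#'
#' @param sites data.frame with columns `chrom`, `pos` (sorted within
#'   chromosome), `diff` (per-CpG case - control mean) and logical `keep`
#'   (presence filter).
#' @param params A [seg_params()].
#' @return data.frame of candidates (chrom, start, end, n_cpgs, mean_diff)
#'   with attribute `site_rows`: list of row indices of `sites` per
#'   candidate.
#' @export
segment_candidates <- function(sites, params = seg_params()) {
  stopifnot(all(c("chrom", "pos", "diff", "keep") %in% names(sites)))
  bad <- tapply(sites$pos, sites$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad))) stop("sites must be sorted by position within chromosome")
  ret <- which(sites$keep)
  out <- list(); rows <- list()
  if (length(ret) > 0) {
    chrom <- sites$chrom[ret]; pos <- sites$pos[ret]
    new_run <- c(TRUE, chrom[-1] != chrom[-length(ret)] |
                   diff(pos) > params$max_gap)
    run_id <- cumsum(new_run)
    for (rid in unique(run_id)) {
      idx <- ret[run_id == rid]
      if (length(idx) < params$min_cpg) next
      leaves <- .split_run(sites$diff[idx], params$min_cpg, params$split_gain)
      for (lv in leaves) {
        sub <- idx[lv[1]:lv[2]]
        rows[[length(rows) + 1L]] <- sub
        out[[length(out) + 1L]] <-
          data.frame(chrom = sites$chrom[sub[1]],
                     start = sites$pos[sub[1]],
                     end = sites$pos[sub[length(sub)]] + 2L,
                     n_cpgs = length(sub),
                     mean_diff = mean(sites$diff[sub]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), mean_diff = numeric())
  rownames(res) <- NULL
  attr(res, "site_rows") <- rows
  res
}

#' Significance thresholds for DMR calling
#'
#' The mark-specific effect-size gates: |methylation difference| > 0.2 for
#' 5mC (and for the combined BS signal), > 0.1 for 5hmC, each combined with
#' BH-adjusted p < 0.05.
#'
#' @param diff_5mc,diff_5hmc,diff_bs Minimum absolute group mean difference.
#' @param q_max Maximum BH-adjusted p-value.
#' @return List of class `dmr_thresholds`.
#' @export
dmr_thresholds <- function(diff_5mc = 0.2, diff_5hmc = 0.1, diff_bs = 0.2,
                           q_max = 0.05) {
  stopifnot(diff_5mc > 0, diff_5hmc > 0, diff_bs > 0, q_max > 0)
  structure(list("5mC" = diff_5mc, "5hmC" = diff_5hmc, "BS" = diff_bs,
                 q_max = q_max),
            class = "dmr_thresholds")
}

#' Is a tested region a significant DMR?
#'
#' @param mean_diff,q Region statistics.
#' @param mark `"5mC"`, `"5hmC"` or `"BS"`.
#' @param thresholds A [dmr_thresholds()].
#' @return Logical vector.
#' @export
dmr_significant <- function(mean_diff, q, mark, thresholds = dmr_thresholds()) {
  q < thresholds$q_max & abs(mean_diff) > thresholds[[mark]]
}

#' Call differentially methylated regions for one mark
#'
#' End-to-end caller: presence filtering, de-novo segmentation
#' ([segment_candidates()]), per-candidate Mann-Whitney tests on per-sample
#' region means ([test_region()]), BH adjustment across all candidates of
#' the (contrast, mark) family, and the mark-specific significance gate.
#'
#' @param pm A `paired_methylome`.
#' @param contrast A [contrast_design()]; defaults to the cohort's own
#'   case/control labels.
#' @param mark `"5mC"`, `"5hmC"` or `"BS"`.
#' @param thresholds A [dmr_thresholds()].
#' @param params A [seg_params()].
#' @return A `dmr_set`: data.frame (chrom, start, end, mark, n_cpgs,
#'   mean_case, mean_control, mean_diff, p, q, direction, significant) with
#'   run tallies in `attr(, "counts")`.
#' @export
call_dmrs <- function(pm, contrast = NULL, mark = c("5mC", "5hmC", "BS"),
                      thresholds = dmr_thresholds(), params = seg_params()) {
  mark <- match.arg(mark)
  if (is.null(contrast)) {
    if (is.null(pm$groups)) stop("no contrast given and cohort has no groups")
    contrast <- contrast_design("case_vs_control",
                                names(pm$groups)[pm$groups == "case"],
                                names(pm$groups)[pm$groups == "control"])
  }
  case <- contrast$case; ctrl <- contrast$control
  if (length(case) < 2L || length(ctrl) < 2L)
    stop("each contrast group needs at least two samples")
  missing_s <- setdiff(c(case, ctrl), colnames(pm$beta_bs))
  if (length(missing_s))
    stop("samples absent from methylome: ", paste(missing_s, collapse = ", "))
  X <- signal_matrix(pm, mark)
  Xc <- X[, case, drop = FALSE]; Xk <- X[, ctrl, drop = FALSE]
  pres_c <- rowMeans(!is.na(Xc)); pres_k <- rowMeans(!is.na(Xk))
  keep <- pres_c >= params$min_group_presence &
    pres_k >= params$min_group_presence
  sites <- data.frame(chrom = pm$map$chrom, pos = pm$map$pos,
                      diff = rowMeans(Xc, na.rm = TRUE) -
                        rowMeans(Xk, na.rm = TRUE),
                      keep = keep)
  sites$diff[is.na(sites$diff)] <- 0
  cand <- segment_candidates(sites, params)
  rows <- attr(cand, "site_rows")
  n_cand <- nrow(cand)
  stats_list <- vector("list", n_cand)
  for (i in seq_len(n_cand)) {
    cv <- colMeans(Xc[rows[[i]], , drop = FALSE], na.rm = TRUE)
    kv <- colMeans(Xk[rows[[i]], , drop = FALSE], na.rm = TRUE)
    cv <- cv[is.finite(cv)]; kv <- kv[is.finite(kv)]
    if (length(cv) < 2L || length(kv) < 2L) next
    tr <- test_region(cv, kv)
    stats_list[[i]] <- c(mean_case = mean(cv), mean_control = mean(kv),
                         mean_diff = tr$mean_diff, p = tr$p)
  }
  tested <- !vapply(stats_list, is.null, TRUE)
  st <- do.call(rbind, stats_list[tested])
  d <- cand[tested, , drop = FALSE]
  if (nrow(d) > 0) {
    d$mark <- mark
    d$mean_case <- st[, "mean_case"]
    d$mean_control <- st[, "mean_control"]
    d$mean_diff <- st[, "mean_diff"]
    d$p <- st[, "p"]
    d$q <- bh_adjust(d$p)
    d$direction <- ifelse(d$mean_diff > 0, "hyper", "hypo")
    d$significant <- dmr_significant(d$mean_diff, d$q, mark, thresholds)
  } else {
    d <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_cpgs = integer(), mean_diff = numeric(),
                    mark = character(), mean_case = numeric(),
                    mean_control = numeric(), p = numeric(), q = numeric(),
                    direction = character(), significant = logical())
  }
  d <- d[, c("chrom", "start", "end", "mark", "n_cpgs", "mean_case",
             "mean_control", "mean_diff", "p", "q", "direction",
             "significant")]
  rownames(d) <- NULL
  structure(d,
            class = c("dmr_set", "data.frame"),
            contrast = contrast$name, mark = mark,
            thresholds = thresholds, params = params,
            site_rows = rows[tested],
            counts = c(n_sites = nrow(sites), n_retained = sum(keep),
                       n_candidates = n_cand, n_tested = sum(tested),
                       n_significant = sum(d$significant),
                       n_hyper = sum(d$significant & d$direction == "hyper"),
                       n_hypo = sum(d$significant & d$direction == "hypo")))
}

#' @export
print.dmr_set <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("dmr_set [%s, contrast '%s']\n", attr(x, "mark"),
              attr(x, "contrast")))
  cat(sprintf("  %d CpGs -> %d retained -> %d candidates -> %d tested\n",
              cnt["n_sites"], cnt["n_retained"], cnt["n_candidates"],
              cnt["n_tested"]))
  cat(sprintf("  significant DMRs: %d (%d hyper / %d hypo)\n",
              cnt["n_significant"], cnt["n_hyper"], cnt["n_hypo"]))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
summary.dmr_set <- function(object, ...) {
  s <- object[object$significant, , drop = FALSE]
  out <- list(mark = attr(object, "mark"), contrast = attr(object, "contrast"),
              counts = attr(object, "counts"),
              direction = table(factor(s$direction, c("hyper", "hypo"))))
  class(out) <- "summary.dmr_set"
  out
}

#' @export
print.summary.dmr_set <- function(x, ...) {
  cat(sprintf("%s DMRs (contrast '%s'): %d significant (%d hyper, %d hypo) of %d tested\n",
              x$mark, x$contrast, x$counts[["n_significant"]],
              x$direction[["hyper"]], x$direction[["hypo"]],
              x$counts[["n_tested"]]))
  invisible(x)
}

#' Volcano-style plot of a DMR set
#'
#' @param x A `dmr_set`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dmr_set <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "mean difference",
                   ylab = "-log10 q", main = attr(x, "mark"))
    return(invisible(x))
  }
  graphics::plot(x$mean_diff, -log10(pmax(x$q, 1e-300)),
                 col = ifelse(x$significant, "red3", "grey50"), pch = 16,
                 xlab = sprintf("mean %s difference (case - control)",
                                attr(x, "mark")),
                 ylab = expression(-log[10] ~ q), ...)
  thr <- attr(x, "thresholds")
  graphics::abline(v = c(-1, 1) * thr[[attr(x, "mark")]], lty = 2)
  graphics::abline(h = -log10(thr$q_max), lty = 2)
  invisible(x)
}
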