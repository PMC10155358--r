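#' Pair BS and oxBS site tables for one sample
#'
#' Inner join on (chrom, pos) with a per-library minimum-coverage filter.
#' Sites absent from either library, or below `min_cov` in either, are
#' dropped; the drop tally is attached as attribute `drops` and reported.
#'
#' @param bs_table,ox_table Site tables from [read_methratio()] for the same
#'   sample (BS and oxBS library respectively).
#' @param min_cov Minimum eligible reads required in each library
#'   (default 5, usual RRBS practice).
#' @return Paired-site data.frame: chrom, pos, beta_bs, beta_ox, c_bs, c_ox,
#'   cov_bs, cov_ox.
#' @export
merge_paired <- function(bs_table, ox_table, min_cov = 5L) {
  m <- merge(bs_table[, c("chrom", "pos", "c_count", "ct_count")],
             ox_table[, c("chrom", "pos", "c_count", "ct_count")],
             by = c("chrom", "pos"), suffixes = c("_bs", "_ox"))
  n_shared <- nrow(m)
  keep <- m$ct_count_bs >= min_cov & m$ct_count_ox >= min_cov
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    beta_bs = m$c_count_bs / m$ct_count_bs,
                    beta_ox = m$c_count_ox / m$ct_count_ox,
                    c_bs = m$c_count_bs, c_ox = m$c_count_ox,
                    cov_bs = m$ct_count_bs, cov_ox = m$ct_count_ox,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  drops <- c(bs_only = nrow(bs_table) - n_shared,
             ox_only = nrow(ox_table) - n_shared,
             low_coverage = n_shared - nrow(out))
  if (nrow(out) == 0L) warning("no shared CpG sites after pairing/filtering")
  attr(out, "drops") <- drops
  out
}

# closed-form constrained MLE of (m, h) from paired binomial counts:
# maximise Bin(c_bs; n_bs, m + h) * Bin(c_ox; n_ox, m) over
# {m >= 0, h >= 0, m + h <= 1}.  Interior solution is (c_ox/n_ox,
# c_bs/n_bs - c_ox/n_ox); when that subtraction is negative the optimum sits
# on the h = 0 face, where both likelihoods share one parameter and the MLE
# is the pooled proportion.
.mle_mh <- function(c_bs, n_bs, c_ox, n_ox) {
  t0 <- c_bs / n_bs
  m0 <- c_ox / n_ox
  m <- ifelse(t0 >= m0, m0, (c_bs + c_ox) / (n_bs + n_ox))
  h <- ifelse(t0 >= m0, t0 - m0, 0)
  list(m = m, h = h)
}

#' Estimate per-CpG 5mC and 5hmC from paired calls
#'
#' The 5hmC level is the plain-bisulfite methylation ratio minus the
#' oxidative-bisulfite ratio (which reflects 5mC only).  Three estimators:
#' \describe{
#'   \item{raw}{`h_hat = beta_bs - beta_ox` (may be negative, unbiased),
#'     `m_hat = beta_ox`.  Default for group-difference and correlation work.}
#'   \item{clamp}{`h_hat = max(0, beta_bs - beta_ox)`,
#'     `m_hat = min(beta_ox, beta_bs)` - for reporting per-sample levels.}
#'   \item{mle}{Joint binomial maximum likelihood constrained to
#'     `m, h >= 0`, `m + h <= 1` (closed form with boundary projection).
#'     Equals the raw subtraction whenever that is already feasible.}
#' }
#'
#' @param paired Paired-site table from [merge_paired()].
#' @param mode `"raw"`, `"clamp"` or `"mle"`.
#' @return `paired` with columns `m_hat`, `h_hat` filled, class `paired_sites`.
#' @export
#' @examples
#' p <- data.frame(chrom = "chr1", pos = 100, beta_bs = 0.9, beta_ox = 0.6,
#'                 c_bs = 9, c_ox = 6, cov_bs = 10, cov_ox = 10)
#' estimate_hmc(p, "raw")$h_hat   # 0.3
estimate_hmc <- function(paired, mode = c("raw", "clamp", "mle")) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    paired$m_hat <- paired$beta_ox
    paired$h_hat <- paired$beta_bs - paired$beta_ox
  } else if (mode == "clamp") {
    paired$m_hat <- pmin(paired$beta_ox, paired$beta_bs)
    paired$h_hat <- pmax(0, paired$beta_bs - paired$beta_ox)
  } else {
    est <- .mle_mh(paired$c_bs, paired$cov_bs, paired$c_ox, paired$cov_ox)
    paired$m_hat <- est$m
    paired$h_hat <- est$h
  }
  attr(paired, "mode") <- mode
  class(paired) <- unique(c("paired_sites", class(paired)))
  paired
}

#' Cohort-level paired methylome
#'
#' Applies the pairing/coverage filter and the chosen 5hmC estimator to every
#' sample of a cohort, yielding aligned CpG x sample matrices of the three
#' analysis signals: `beta_ox` (5mC), `h_hat` (5hmC) and `beta_bs`
#' (combined bisulfite signal).  Entries failing the coverage filter in
#' either library are `NA`.
#'
#' @param cohort A `meth_cohort`.
#' @param min_cov Minimum coverage in each library (default 5).
#' @param mode 5hmC estimator, see [estimate_hmc()].
#' @return Object of class `paired_methylome`: list with `map`, matrices
#'   `beta_bs`, `beta_ox`, `m_hat`, `h_hat`, `cov_bs`, `cov_ox`, plus
#'   `groups`, `mode`, `min_cov`.
#' @export
estimate_cohort <- function(cohort, min_cov = 5L, mode = c("raw", "clamp", "mle")) {
  mode <- match.arg(mode)
  cnt <- cohort$counts
  ok <- cnt$bs_n >= min_cov & cnt$ox_n >= min_cov
  bb <- cnt$bs_c / cnt$bs_n
  bo <- cnt$ox_c / cnt$ox_n
  bb[!ok] <- NA_real_; bo[!ok] <- NA_real_
  if (mode == "raw") {
    m <- bo; h <- bb - bo
  } else if (mode == "clamp") {
    m <- pmin(bo, bb); h <- pmax(bb - bo, 0)
  } else {
    est <- .mle_mh(cnt$bs_c, cnt$bs_n, cnt$ox_c, cnt$ox_n)
    m <- est$m; h <- est$h
    m[!ok] <- NA_real_; h[!ok] <- NA_real_
  }
  structure(list(map = cohort$map, beta_bs = bb, beta_ox = bo,
                 m_hat = m, h_hat = h,
                 cov_bs = cnt$bs_n, cov_ox = cnt$ox_n,
                 groups = cohort$groups, mode = mode,
                 min_cov = as.integer(min_cov)),
            class = "paired_methylome")
}

#' @export
print.paired_methylome <- function(x, ...) {
  cat(sprintf("paired_methylome: %d CpGs x %d samples (mode = %s, min_cov = %d)\n",
              nrow(x$map), ncol(x$beta_bs), x$mode, x$min_cov))
  cat(sprintf("  callable entries: %.1f%%\n",
              100 * mean(!is.na(x$beta_bs))))
  invisible(x)
}

#' Extract the analysis signal matrix for a mark
#'
#' `"5mC"` is the oxBS ratio, `"5hmC"` the subtraction estimate and `"BS"`
#' the plain-bisulfite ratio (5mC + 5hmC combined).
#'
#' @param pm A `paired_methylome`.
#' @param mark One of `"5mC"`, `"5hmC"`, `"BS"`.
#' @return CpG x sample numeric matrix.
#' @export
signal_matrix <- function(pm, mark = c("5mC", "5hmC", "BS")) {
  mark <- match.arg(mark)
  switch(mark, "5mC" = pm$beta_ox, "5hmC" = pm$h_hat, "BS" = pm$beta_bs)
}

#' Write per-sample paired-site tables
#'
#' One TSV per sample: chrom, pos, beta_bs, beta_ox, h_hat, m_hat, cov_bs,
#' cov_ox (callable sites only).
#'
#' @param pm A `paired_methylome`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_paired_tables <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (s in colnames(pm$beta_bs)) {
    keep <- !is.na(pm$beta_bs[, s])
    d <- data.frame(chrom = pm$map$chrom[keep], pos = pm$map$pos[keep],
                    beta_bs = sprintf("%.17g", pm$beta_bs[keep, s]),
                    beta_ox = sprintf("%.17g", pm$beta_ox[keep, s]),
                    h_hat = sprintf("%.17g", pm$h_hat[keep, s]),
                    m_hat = sprintf("%.17g", pm$m_hat[keep, s]),
                    cov_bs = pm$cov_bs[keep, s], cov_ox = pm$cov_ox[keep, s])
    p <- file.path(dir, sprintf("%s_paired.tsv", s))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read paired-site tables back into a `paired_methylome`
#'
#' @param paths Named character vector of per-sample paired TSVs (names =
#'   sample ids), as written by [write_paired_tables()].
#' @param groups Optional named case/control vector.
#' @param mode Estimator label to record.
#' @param min_cov Coverage filter to record.
#' @return A `paired_methylome`.
#' @export
read_paired_tables <- function(paths, groups = NULL, mode = "raw", min_cov = 5L) {
  stopifnot(!is.null(names(paths)))
  tabs <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE)
  keys <- unique(unlist(lapply(tabs, function(t) paste(t$chrom, t$pos))))
  km <- do.call(rbind, strsplit(keys, " "))
  map <- data.frame(chrom = km[, 1], pos = as.integer(km[, 2]), strand = "+",
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos), ]; rownames(map) <- NULL
  key <- paste(map$chrom, map$pos)
  mk <- function(fill = NA_real_) matrix(fill, nrow(map), length(paths),
                                         dimnames = list(NULL, names(paths)))
  bb <- mk(); bo <- mk(); h <- mk(); m <- mk(); nb <- mk(0); no <- mk(0)
  for (s in names(paths)) {
    t <- tabs[[s]]
    j <- match(paste(t$chrom, t$pos), key)
    bb[j, s] <- t$beta_bs; bo[j, s] <- t$beta_ox
    h[j, s] <- t$h_hat; m[j, s] <- t$m_hat
    nb[j, s] <- t$cov_bs; no[j, s] <- t$cov_ox
  }
  structure(list(map = map, beta_bs = bb, beta_ox = bo, m_hat = m, h_hat = h,
                 cov_bs = nb, cov_ox = no, groups = groups, mode = mode,
                 min_cov = as.integer(min_cov)),
            class = "paired_methylome")
}
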