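#' Conversion-chemistry parameters for BS/oxBS libraries
#'
#' Bisulfite converts unmodified cytosine to uracil (read as T) while 5mC and
#' 5hmC are protected; prior chemical oxidation (oxBS) additionally converts
#' 5hmC so that it reads as T.  These three rates describe the imperfections
#' of that chemistry.
#'
#' @param eps_fail Probability an unmodified C escapes conversion and still
#'   reads as C (bisulfite non-conversion rate).
#' @param eps_over Probability a protected (5mC/5hmC) base is over-converted
#'   and reads as T.
#' @param eta_ox Probability the oxidation step converts a 5hmC so that it
#'   reads as T in the oxBS library (oxidation efficiency).
#' @return An object of class `chemistry_params`.
#' @export
#' @examples
#' chemistry_params()                      # defaults
#' chemistry_params(0, 0, 1)               # perfect chemistry
chemistry_params <- function(eps_fail = 0.005, eps_over = 0.005, eta_ox = 0.95) {
  p <- c(eps_fail = eps_fail, eps_over = eps_over, eta_ox = eta_ox)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("chemistry parameters must all lie in [0, 1]")
  structure(as.list(p), class = "chemistry_params")
}

#' Probability that a sequenced read reports C at a CpG
#'
#' Maps true modification levels (m = 5mC, h = 5hmC) through the conversion
#' chemistry of a BS or oxBS library to the expected proportion of reads
#' retaining C.  In a BS library both marks are protected; in an oxBS library
#' 5hmC is converted with probability `eta_ox`.
#'
#' @param m True 5mC level(s) in \[0, 1\] (vectorised).
#' @param h True 5hmC level(s) in \[0, 1\]; requires `m + h <= 1`.
#' @param library `"BS"` or `"oxBS"`.
#' @param chem A [chemistry_params()] object.
#' @return Numeric vector of read-level C probabilities in \[0, 1\].
#' @export
#' @examples
#' expected_read_probability(0.6, 0.3, "BS", chemistry_params(0, 0, 1))    # 0.9
#' expected_read_probability(0.6, 0.3, "oxBS", chemistry_params(0, 0, 1))  # 0.6
expected_read_probability <- function(m, h, library = c("BS", "oxBS"),
                                      chem = chemistry_params()) {
  library <- match.arg(library)
  if (any(m < -1e-12) || any(h < -1e-12) || any(m + h > 1 + 1e-9))
    stop("levels must satisfy m >= 0, h >= 0, m + h <= 1")
  u <- 1 - m - h
  p <- if (library == "BS") {
    (m + h) * (1 - chem$eps_over) + u * chem$eps_fail
  } else {
    m * (1 - chem$eps_over) + h * (1 - chem$eta_ox) * (1 - chem$eps_over) +
      u * chem$eps_fail
  }
  pmin(pmax(p, 0), 1)
}

#' CpG spacing model for the synthetic reference
#'
#' RRBS coverage concentrates in MspI-fragment CpG clusters (island-like
#' stretches of closely spaced CpGs separated by long uncovered gaps), so the
#' default spacing is clustered.
#'
#' @param type `"clustered"` (CpG-island-like) or `"fixed"` (uniform spacing).
#' @param cluster_size CpGs per cluster (clusters are also the unit at which
#'   per-sample biological jitter is applied, see [simulate_counts()]).
#' @param within Mean gap in bp between neighbouring CpGs in a cluster
#'   (exact gap for `type = "fixed"`).
#' @param between Gap in bp between clusters.
#' @return An object of class `spacing_spec`.
#' @export
spacing_spec <- function(type = c("clustered", "fixed"), cluster_size = 10L,
                         within = 50, between = 5000) {
  type <- match.arg(type)
  stopifnot(cluster_size >= 1, within >= 2, between >= 2)
  structure(list(type = type, cluster_size = as.integer(cluster_size),
                 within = within, between = between),
            class = "spacing_spec")
}

#' Negative-binomial coverage model
#'
#' Per-site, per-library sequencing depth is drawn independently for the BS
#' and oxBS libraries (they are separate preparations) from a negative
#' binomial with mean `mean` and size `size` (variance `mu + mu^2/size`),
#' reflecting the overdispersion of RRBS depth.
#'
#' @param mean Mean depth per CpG per library.
#' @param size Negative-binomial size (smaller = more overdispersed).
#' @return An object of class `coverage_spec`.
#' @export
coverage_spec <- function(mean = 30, size = 8) {
  stopifnot(mean >= 0, size > 0)
  structure(list(mean = mean, size = size), class = "coverage_spec")
}

#' Baseline modification-level model
#'
#' True per-CpG 5mC baselines are drawn from a two-component Beta mixture
#' (a low-methylation, promoter/island-like component and a high-methylation,
#' gene-body-like component, giving the familiar bimodal beta-value
#' distribution); 5hmC baselines from a single low-mean Beta, then clipped so
#' that `m + h <= 1`.
#'
#' @param m_weights Mixture weights for the 5mC components.
#' @param m_shape1,m_shape2 Beta shape vectors, one entry per component.
#' @param h_shape1,h_shape2 Beta shapes for the 5hmC baseline.
#' @param fixed_m,fixed_h Optional constants overriding the random baselines
#'   (handy for calibration studies with known truth).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(m_weights = c(0.5, 0.5),
                          m_shape1 = c(1, 8), m_shape2 = c(10, 2),
                          h_shape1 = 1.2, h_shape2 = 15,
                          fixed_m = NULL, fixed_h = NULL) {
  stopifnot(length(m_weights) == length(m_shape1),
            length(m_weights) == length(m_shape2),
            all(m_weights >= 0), sum(m_weights) > 0)
  structure(list(m_weights = m_weights / sum(m_weights),
                 m_shape1 = m_shape1, m_shape2 = m_shape2,
                 h_shape1 = h_shape1, h_shape2 = h_shape2,
                 fixed_m = fixed_m, fixed_h = fixed_h),
            class = "baseline_spec")
}

#' Simulate a CpG map and minimal gene model
#'
#' Generates strictly increasing CpG positions per chromosome (0-based
#' internal convention, one record per collapsed CpG dyad on the + strand)
#' together with a small deterministic gene model whose transcripts are laid
#' out so that every annotation category (promoter, exon, TTS, intron,
#' intergenic) contains CpGs.
#'
#' @param n_chromosomes,cpgs_per_chromosome Counts, both >= 1.
#' @param spacing A [spacing_spec()].
#' @param seed Integer seed; identical calls are reproducible byte-for-byte.
#' @return A list with elements `map` (data.frame: chrom, pos, strand,
#'   cluster) and `genes` (a [gene_model()] object, possibly empty for very
#'   small maps).
#' @export
simulate_reference <- function(n_chromosomes, cpgs_per_chromosome,
                               spacing = spacing_spec(), seed = 1L) {
  if (n_chromosomes < 1 || cpgs_per_chromosome < 1)
    stop("need at least one chromosome and one CpG per chromosome")
  set.seed(as.integer(seed))
  maps <- vector("list", n_chromosomes)
  cl_offset <- 0L
  for (ci in seq_len(n_chromosomes)) {
    n <- as.integer(cpgs_per_chromosome)
    cluster <- ((seq_len(n) - 1L) %/% spacing$cluster_size) + 1L
    new_cluster <- c(FALSE, diff(cluster) > 0)
    if (spacing$type == "fixed") {
      gaps <- rep(spacing$within, n - 1L)
    } else {
      gaps <- 2 + stats::rpois(max(n - 1L, 0L), spacing$within - 2)
      gaps[new_cluster[-1L]] <- spacing$between +
        round(stats::runif(sum(new_cluster), 0, spacing$between / 2))
    }
    pos <- cumsum(c(1000, gaps))
    maps[[ci]] <- data.frame(chrom = sprintf("chr%d", ci),
                             pos = as.integer(pos), strand = "+",
                             cluster = cluster + cl_offset,
                             stringsAsFactors = FALSE)
    cl_offset <- cl_offset + max(cluster)
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  list(map = map, genes = .reference_gene_model(map))
}

# Deterministic gene model over CpG clusters: blocks of 4 clusters host one
# transcript (promoter at cluster 1, exon/intron over clusters 1-2, TTS
# window over the tail of cluster 3), cluster 4 stays intergenic.  Strand
# alternates between blocks.
.reference_gene_model <- function(map) {
  tx <- list(); ex <- list(); k <- 0L
  for (chrom in unique(map$chrom)) {
    sub <- map[map$chrom == chrom, ]
    cls <- unique(sub$cluster)
    n_blocks <- length(cls) %/% 4L
    for (b in seq_len(n_blocks)) {
      c3 <- cls[(b - 1L) * 4L + 1:3]
      p1 <- sub$pos[sub$cluster == c3[1]]
      p2 <- sub$pos[sub$cluster == c3[2]]
      p3 <- sub$pos[sub$cluster == c3[3]]
      mid3 <- p3[ceiling(length(p3) / 2)]
      k <- k + 1L
      strand <- if (b %% 2L == 1L) "+" else "-"
      if (strand == "+") {
        txs <- min(p1); txe <- mid3 + 1L
        exons <- rbind(c(min(p1), max(p1) + 2L),
                       c(min(p2), min(p2) + 120L))
      } else {
        # mirrored layout: TSS at the right end, TTS window at cluster 1
        mid1 <- p1[ceiling(length(p1) / 2)]
        txs <- mid1; txe <- max(p3) + 2L
        exons <- rbind(c(max(p2) - 120L, max(p2) + 2L),
                       c(min(p3), max(p3) + 2L))
      }
      id <- sprintf("%s_tx%d", chrom, k)
      tx[[k]] <- data.frame(tx_id = id, chrom = chrom, start = txs, end = txe,
                            strand = strand, stringsAsFactors = FALSE)
      ex[[k]] <- data.frame(tx_id = id, chrom = chrom,
                            start = exons[, 1], end = exons[, 2],
                            stringsAsFactors = FALSE)
    }
  }
  if (length(tx) == 0L)
    return(gene_model(data.frame(tx_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character()),
                      data.frame(tx_id = character(), chrom = character(),
                                 start = integer(), end = integer())))
  gene_model(do.call(rbind, tx), do.call(rbind, ex))
}

#' Planted region-level group effects
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param mark `"5mC"` or `"5hmC"`: which mark receives `delta`.
#' @param delta Signed level shift applied to case-group samples.
#' @param coupling Signed shift applied to the *other* mark in the same
#'   samples; negative coupling plants the anti-correlated 5mC/5hmC
#'   alterations the subtraction-based analyses are sensitive to.
#' @return data.frame with one row per effect, class `region_effects`.
#' @export
region_effects <- function(chrom, start, end, mark, delta, coupling = 0) {
  d <- data.frame(chrom = chrom, start = as.integer(start),
                  end = as.integer(end), mark = mark,
                  delta = delta, coupling = coupling,
                  stringsAsFactors = FALSE)
  if (any(!d$mark %in% c("5mC", "5hmC"))) stop("mark must be 5mC or 5hmC")
  if (any(abs(d$delta) > 1) || any(abs(d$coupling) > 1))
    stop("|delta| and |coupling| must be <= 1")
  if (any(d$end <= d$start)) stop("end must exceed start")
  class(d) <- c("region_effects", "data.frame")
  d
}

#' Place effects on CpG clusters of a simulated map
#'
#' Assigns each requested effect to its own CpG cluster (round-robin over
#' evenly spaced clusters) so planted regions are disjoint and align with
#' the RRBS-like coverage islands.
#'
#' @param map CpG map from [simulate_reference()] (needs a `cluster` column).
#' @param spec data.frame with columns `mark`, `delta`, `coupling`, `n`
#'   (number of regions of that kind to plant).
#' @param skip Plant on every `skip`-th cluster (leaves null clusters between
#'   planted ones).
#' @return A [region_effects()] data.frame covering whole clusters.
#' @export
plant_effects <- function(map, spec, skip = 2L) {
  stopifnot(!is.null(map$cluster))
  total <- sum(spec$n)
  cls <- unique(map$cluster)
  use <- cls[seq(1L, by = as.integer(skip), length.out = total)]
  if (anyNA(use) || total > length(cls))
    stop("not enough CpG clusters to plant the requested effects")
  rows <- rep(seq_len(nrow(spec)), spec$n)
  out <- lapply(seq_along(use), function(i) {
    p <- map$pos[map$cluster == use[i]]
    region_effects(map$chrom[map$cluster == use[i]][1], min(p), max(p) + 2L,
                   spec$mark[rows[i]], spec$delta[rows[i]],
                   spec$coupling[rows[i]])
  })
  do.call(rbind, out)
}

#' Ground-truth specification for a synthetic paired BS/oxBS cohort
#'
#' @param map CpG map (data.frame chrom, pos, strand and optionally cluster),
#'   positions strictly increasing within each chromosome.
#' @param groups Named character vector mapping sample id to `"case"` or
#'   `"control"`.
#' @param regions Optional [region_effects()] planted in case samples.
#' @param baseline A [baseline_spec()].
#' @param coverage A [coverage_spec()].
#' @param chemistry A [chemistry_params()].
#' @param sample_sd Named vector `c(m = , h = )`: standard deviation of the
#'   per-sample, per-cluster Gaussian jitter on true levels (biological
#'   inter-individual variability; applied before clipping to the simplex).
#' @param seed Integer seed.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(map, groups, regions = NULL,
                       baseline = baseline_spec(),
                       coverage = coverage_spec(),
                       chemistry = chemistry_params(),
                       sample_sd = c(m = 0.10, h = 0.05),
                       seed = 1L) {
  stopifnot(is.data.frame(map), all(c("chrom", "pos") %in% names(map)))
  bad <- tapply(map$pos, map$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad))) stop("positions must be strictly increasing within a chromosome")
  if (is.null(names(groups)) || anyNA(groups) ||
      !all(groups %in% c("case", "control")))
    stop("groups must be a named vector of 'case'/'control'")
  if (length(unique(names(groups))) != length(groups))
    stop("duplicated sample ids in groups")
  if (!is.null(regions)) {
    if (any(abs(regions$delta) > 1)) stop("|delta| must be <= 1")
  }
  structure(list(map = map, groups = groups, regions = regions,
                 baseline = baseline, coverage = coverage,
                 chemistry = chemistry, sample_sd = sample_sd,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

.draw_baseline <- function(n, b) {
  if (!is.null(b$fixed_m) || !is.null(b$fixed_h)) {
    m <- rep(if (is.null(b$fixed_m)) 0 else b$fixed_m, n)
    h <- rep(if (is.null(b$fixed_h)) 0 else b$fixed_h, n)
    if (any(m + h > 1)) stop("fixed baselines violate m + h <= 1")
    return(list(m = m, h = h))
  }
  comp <- sample.int(length(b$m_weights), n, replace = TRUE, prob = b$m_weights)
  m <- stats::rbeta(n, b$m_shape1[comp], b$m_shape2[comp])
  h <- stats::rbeta(n, b$h_shape1, b$h_shape2)
  h <- pmin(h, 1 - m)
  list(m = m, h = h)
}

# Baselines with headroom for a planted (delta_m, delta_h) shift: real DMRs
# of a given magnitude live at loci able to shift by it, so region CpGs get
# intermediate levels drawn uniformly from the feasible simplex slice
# {m0 >= max(0,-dm), h0 >= max(0,-dh), m0 + h0 <= 1 - max(0, dm + dh)}.
.draw_region_baseline <- function(n, dm, dh, pad_m = 0.1, pad_h = 0.05) {
  h_lo <- max(0, -dh)
  m_lo <- max(0, -dm)
  tot_hi <- 1 - max(0, dm + dh)
  h_hi <- min(0.3 + h_lo, tot_hi - m_lo)   # keep 5hmC in its realistic range
  pad_h <- min(pad_h, max(0, (h_hi - h_lo) / 4))
  h <- stats::runif(n, h_lo + pad_h, max(h_lo + pad_h, h_hi - pad_h))
  m_hi <- pmax(m_lo, tot_hi - h)
  pad <- pmin(pad_m, (m_hi - m_lo) / 4)
  m <- stats::runif(n, m_lo + pad, pmax(m_lo + pad, m_hi - pad))
  list(m = m, h = h)
}

#' Simulate paired BS/oxBS read counts for a cohort
#'
#' Draws true per-CpG (m, h) baselines, applies planted region effects to the
#' case group, adds per-sample per-cluster biological jitter, clips to the
#' simplex `m, h >= 0, m + h <= 1`, draws independent negative-binomial
#' coverage for the BS and oxBS libraries, and samples methylated read counts
#' as Binomial(coverage, [expected_read_probability()]).
#'
#' @param spec A [truth_spec()].
#' @return A `meth_cohort` object: list with `map`, `counts`
#'   (matrices `bs_c`, `bs_n`, `ox_c`, `ox_n`, CpGs x samples), `truth`
#'   (per-sample true `m`, `h` matrices), `groups`, `regions`, `chemistry`,
#'   `seed`.
#' @export
simulate_counts <- function(spec) {
  if (!inherits(spec, "truth_spec")) stop("spec must be a truth_spec")
  set.seed(spec$seed)
  map <- spec$map
  n <- nrow(map)
  samples <- names(spec$groups)
  S <- length(samples)
  base <- .draw_baseline(n, spec$baseline)
  M <- matrix(base$m, n, S)
  H <- matrix(base$h, n, S)
  colnames(M) <- colnames(H) <- samples
  is_case <- spec$groups == "case"
  if (!is.null(spec$regions)) {
    for (i in seq_len(nrow(spec$regions))) {
      r <- spec$regions[i, ]
      idx <- which(map$chrom == r$chrom & map$pos >= r$start & map$pos < r$end)
      dm <- if (r$mark == "5mC") r$delta else r$coupling
      dh <- if (r$mark == "5mC") r$coupling else r$delta
      rb <- .draw_region_baseline(length(idx), dm, dh)
      M[idx, ] <- rb$m; H[idx, ] <- rb$h
      M[idx, is_case] <- M[idx, is_case] + dm
      H[idx, is_case] <- H[idx, is_case] + dh
    }
  }
  cluster <- if (!is.null(map$cluster)) map$cluster else rep(1L, n)
  cl_idx <- match(cluster, unique(cluster))
  ncl <- max(cl_idx)
  if (spec$sample_sd[["m"]] > 0 || spec$sample_sd[["h"]] > 0) {
    jm <- matrix(stats::rnorm(ncl * S, 0, spec$sample_sd[["m"]]), ncl, S)
    jh <- matrix(stats::rnorm(ncl * S, 0, spec$sample_sd[["h"]]), ncl, S)
    M <- M + jm[cl_idx, , drop = FALSE]
    H <- H + jh[cl_idx, , drop = FALSE]
  }
  M <- pmin(pmax(M, 0), 1)
  H <- pmax(H, 0)
  H <- pmin(H, 1 - M)
  nb <- function() {
    if (spec$coverage$mean == 0) return(matrix(0L, n, S))
    matrix(stats::rnbinom(n * S, mu = spec$coverage$mean,
                          size = spec$coverage$size), n, S)
  }
  bs_n <- nb(); ox_n <- nb()
  p_bs <- expected_read_probability(M, H, "BS", spec$chemistry)
  p_ox <- expected_read_probability(M, H, "oxBS", spec$chemistry)
  bs_c <- matrix(stats::rbinom(n * S, as.vector(bs_n), as.vector(p_bs)), n, S)
  ox_c <- matrix(stats::rbinom(n * S, as.vector(ox_n), as.vector(p_ox)), n, S)
  dimnames(bs_c) <- dimnames(bs_n) <- dimnames(ox_c) <- dimnames(ox_n) <-
    list(NULL, samples)
  structure(list(map = map,
                 counts = list(bs_c = bs_c, bs_n = bs_n,
                               ox_c = ox_c, ox_n = ox_n),
                 truth = list(m = M, h = H),
                 groups = spec$groups, regions = spec$regions,
                 chemistry = spec$chemistry, seed = spec$seed),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("meth_cohort: %d CpGs x %d samples (%d case / %d control)\n",
              nrow(x$map), length(x$groups),
              sum(x$groups == "case"), sum(x$groups == "control")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$map$chrom), collapse = ", ")))
  if (!is.null(x$regions))
    cat(sprintf("  planted effects: %d (%s)\n", nrow(x$regions),
                paste(sprintf("%d %s", table(x$regions$mark),
                              names(table(x$regions$mark))), collapse = ", ")))
  if (!is.null(x$truth)) cat("  ground truth retained\n")
  invisible(x)
}
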