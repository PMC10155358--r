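#' Read a methratio-style per-CpG methylation call table
#'
#' Parses the tab-separated per-site output of BSMAP-style methylation
#' callers: one row per cytosine with 1-based position, strand, sequence
#' context, methylation ratio and read counts.  Only CpG-context rows are
#' kept; file positions are converted to the package-internal 0-based
#' convention; by default records on the two strands of a CpG dyad
#' (positions pos, pos+1) are collapsed into one record by summing counts.
#'
#' @param path File path (TSV, with or without a header line).
#' @param col_names Column order when the file is headerless.  When a header
#'   is present the named columns are used directly.
#' @param collapse_strands Merge +/- dyad records by summing counts
#'   (default TRUE).
#' @return data.frame with columns chrom, pos (0-based), strand, c_count,
#'   ct_count, ratio.  The number of malformed/rejected rows is reported via
#'   a warning and attached as attribute `n_dropped`.
#' @export
read_methratio <- function(path,
                           col_names = c("chrom", "pos", "strand", "context",
                                         "ratio", "c_count", "ct_count"),
                           collapse_strands = TRUE) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty methratio file: ", path)
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), c_count = integer(),
                      ct_count = integer(), ratio = numeric())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  has_header <- grepl("chr(om)?\\b", strsplit(first, "\t")[[1]][1],
                      ignore.case = TRUE) &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  d <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(d) < length(col_names))
      stop("methratio file has fewer columns than expected: ", path)
    names(d)[seq_along(col_names)] <- col_names
  }
  need <- c("chrom", "pos", "strand", "c_count", "ct_count")
  if (!all(need %in% names(d)))
    stop("methratio file missing mandatory columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  n0 <- nrow(d)
  if ("context" %in% names(d)) d <- d[d$context %in% c("CG", "CpG"), ]
  bad <- !is.finite(d$pos) | !is.finite(d$c_count) | !is.finite(d$ct_count) |
    d$ct_count <= 0 | d$c_count < 0
  over <- !bad & d$c_count > d$ct_count
  if (any(over))
    warning(sum(over), " row(s) with c_count > ct_count rejected in ", path)
  d <- d[!bad & !over, , drop = FALSE]
  n_dropped <- n0 - nrow(d)
  d$pos <- as.integer(d$pos) - 1L     # 1-based file -> 0-based internal
  if (collapse_strands && any(d$strand == "-")) {
    d$pos[d$strand == "-"] <- d$pos[d$strand == "-"] - 1L
    key <- paste(d$chrom, d$pos)
    c_count <- rowsum(d$c_count, key)
    ct_count <- rowsum(d$ct_count, key)
    u <- !duplicated(key)
    d <- data.frame(chrom = d$chrom[u], pos = d$pos[u],
                    strand = "+", stringsAsFactors = FALSE)
    ord <- match(paste(d$chrom, d$pos), rownames(c_count))
    d$c_count <- as.integer(c_count[ord, 1])
    d$ct_count <- as.integer(ct_count[ord, 1])
  } else {
    d <- d[, c("chrom", "pos", "strand", "c_count", "ct_count")]
  }
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  d$ratio <- d$c_count / d$ct_count
  if (n_dropped > 0 && !any(over))
    message(n_dropped, " malformed/non-CpG row(s) dropped from ", path)
  attr(d, "n_dropped") <- as.integer(n_dropped)
  d
}

#' Write a site table in methratio format
#'
#' Inverse of [read_methratio()]: positions are written 1-based, context
#' `CG`, with a header line.
#'
#' @param tbl Site table (chrom, pos, strand, c_count, ct_count, ratio).
#' @param path Output path.
#' @export
write_methratio <- function(tbl, path) {
  out <- data.frame(chrom = tbl$chrom, pos = tbl$pos + 1L,
                    strand = if (is.null(tbl$strand)) "+" else tbl$strand,
                    context = "CG",
                    ratio = sprintf("%.6g", tbl$c_count / tbl$ct_count),
                    c_count = tbl$c_count, ct_count = tbl$ct_count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group contrast design
#'
#' @param name Contrast label.
#' @param case,control Character vectors of sample ids (both non-empty,
#'   disjoint).
#' @return Object of class `contrast_design`.
#' @export
contrast_design <- function(name, case, control) {
  if (length(case) == 0L || length(control) == 0L)
    stop("both contrast groups must be non-empty")
  all_s <- c(case, control)
  if (anyDuplicated(all_s)) stop("each sample may appear in only one group")
  structure(list(name = name, case = as.character(case),
                 control = as.character(control)),
            class = "contrast_design")
}

#' @export
print.contrast_design <- function(x, ...) {
  cat(sprintf("contrast '%s': %d case vs %d control\n",
              x$name, length(x$case), length(x$control)))
  invisible(x)
}

#' Median split of a per-sample expression value into high/low groups
#'
#' Samples strictly above the cohort median become the case ("high") group;
#' samples at or below the median the control ("low") group (ties at the
#' median go to low; configurable via `ties`).
#'
#' @param expression Named numeric vector (names = sample ids), >= 2 samples.
#' @param name Contrast label.
#' @param ties `"low"` (default) or `"high"`: where samples exactly at the
#'   median are assigned.
#' @return A [contrast_design()] with case = high, control = low.
#' @export
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))  # high = c,d
median_split <- function(expression, name = "high_vs_low", ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(expression) < 2L) stop("median split needs at least two samples")
  if (is.null(names(expression))) stop("expression values must be named by sample")
  med <- stats::median(expression)
  hi <- if (ties == "low") expression > med else expression >= med
  if (all(hi) || !any(hi))
    stop("degenerate contrast: all expression values on one side of the median")
  contrast_design(name, names(expression)[hi], names(expression)[!hi])
}

#' Parse a genome-browser region string
#'
#' Converts a 1-based inclusive browser coordinate string such as
#' `"chr18:79,461,612-79,461,992"` to the internal 0-based half-open
#' convention.
#'
#' @param x Region string(s); commas and en-dashes tolerated.
#' @return data.frame(chrom, start, end) with 0-based half-open coordinates.
#' @export
parse_region_string <- function(x) {
  x <- gsub(",", "", x)
  x <- gsub("–", "-", x)
  m <- regmatches(x, regexec("^(\\S+?):(\\d+)-(\\d+)$", x))
  if (any(vapply(m, length, 1L) != 4L)) stop("malformed region string")
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)) - 1L,
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

.dmr_bed_cols <- c("mark", "n_cpgs", "mean_case", "mean_control",
                   "mean_diff", "p", "q", "direction", "significant")

#' Write DMRs as a BED6+ file
#'
#' Standard 0-based half-open BED with name/score/strand columns followed by
#' the DMR statistics (mark, CpG count, group means, difference, p, q,
#' direction, significance flag).  Input is sorted on write; a commented
#' header line names the columns so [read_dmr_bed()] round-trips exactly.
#'
#' @param dmrs A `dmr_set` (or compatible data.frame).
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  cols <- intersect(.dmr_bed_cols, names(dmrs))
  d <- as.data.frame(dmrs)[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  header <- paste0("#", paste(c("chrom", "start", "end", "name", "score",
                                "strand", cols), collapse = "\t"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  if (nrow(d) > 0) {
    num <- function(v) if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    body <- cbind(d$chrom, d$start, d$end,
                  sprintf("dmr_%d", seq_len(nrow(d))), 0L, ".",
                  do.call(cbind, lapply(d[cols], num)))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a BED6+ DMR file written by [write_dmr_bed()]
#'
#' @param path File path.
#' @return data.frame with chrom, start, end and any extra statistic columns.
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t")[[1]]
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L) {
    d <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  } else {
    d <- utils::read.delim(text = body, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  }
  for (v in intersect(c("start", "end", "n_cpgs"), names(d)))
    d[[v]] <- as.integer(d[[v]])
  for (v in intersect(c("mean_case", "mean_control", "mean_diff", "p", "q"),
                      names(d)))
    d[[v]] <- as.numeric(d[[v]])
  if ("significant" %in% names(d)) d$significant <- as.logical(d$significant)
  d[, setdiff(names(d), c("name", "score", "strand")), drop = FALSE]
}

#' Read a cohort sample sheet
#'
#' CSV with at least `sample_id`, `path_bs`, `path_ox`; any further columns
#' are kept as per-sample annotation (group labels, expression values).
#' Relative library paths are resolved against the sheet's directory.
#'
#' @param path CSV path.
#' @return data.frame of samples.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path_bs", "path_ox")
  if (!all(need %in% names(d)))
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicated sample ids in sample sheet")
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  d$path_bs <- fix(d$path_bs); d$path_ox <- fix(d$path_ox)
  d
}

#' Write a simulated cohort to methratio files plus sample sheet
#'
#' One BS and one oxBS methratio TSV per sample, a `sample_sheet.csv`
#' pointing at them (with the group labels), and, when planted effects are
#' present, a `truth_regions.bed` of the ground-truth intervals.
#'
#' @param cohort A `meth_cohort`.
#' @param dir Output directory (created if needed).
#' @return The sample-sheet path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- names(cohort$groups)
  sheet <- data.frame(sample_id = samples,
                      path_bs = sprintf("%s_BS.tsv", samples),
                      path_ox = sprintf("%s_oxBS.tsv", samples),
                      group = unname(cohort$groups))
  for (i in seq_along(samples)) {
    keep_bs <- cohort$counts$bs_n[, i] > 0
    write_methratio(data.frame(chrom = cohort$map$chrom,
                               pos = cohort$map$pos, strand = "+",
                               c_count = cohort$counts$bs_c[, i],
                               ct_count = cohort$counts$bs_n[, i])[keep_bs, ],
                    file.path(dir, sheet$path_bs[i]))
    keep_ox <- cohort$counts$ox_n[, i] > 0
    write_methratio(data.frame(chrom = cohort$map$chrom,
                               pos = cohort$map$pos, strand = "+",
                               c_count = cohort$counts$ox_c[, i],
                               ct_count = cohort$counts$ox_n[, i])[keep_ox, ],
                    file.path(dir, sheet$path_ox[i]))
  }
  utils::write.csv(sheet, file.path(dir, "sample_sheet.csv"), row.names = FALSE)
  if (!is.null(cohort$regions)) {
    r <- cohort$regions
    utils::write.table(data.frame(r$chrom, r$start, r$end,
                                  paste0(r$mark, "_delta", r$delta), 0, "+"),
                       file.path(dir, "truth_regions.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(file.path(dir, "sample_sheet.csv"))
}

#' Assemble a cohort from methratio files listed in a sample sheet
#'
#' Reads every sample's BS and oxBS tables, takes the union of CpG sites and
#' builds count matrices (absent sites get zero coverage).
#'
#' @param sheet Path to a sample sheet, or an equivalent data.frame.
#' @param groups Optional named case/control vector; defaults to the sheet's
#'   `group` column when present.
#' @param collapse_strands Passed to [read_methratio()].
#' @return A `meth_cohort` (without ground truth).
#' @export
read_cohort <- function(sheet, groups = NULL, collapse_strands = TRUE) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  samples <- sheet$sample_id
  tabs <- lapply(seq_len(nrow(sheet)), function(i) {
    list(bs = read_methratio(sheet$path_bs[i], collapse_strands = collapse_strands),
         ox = read_methratio(sheet$path_ox[i], collapse_strands = collapse_strands))
  })
  keys <- unique(unlist(lapply(tabs, function(t)
    c(paste(t$bs$chrom, t$bs$pos), paste(t$ox$chrom, t$ox$pos)))))
  if (length(keys) == 0L) stop("no CpG sites found in any library")
  km <- do.call(rbind, strsplit(keys, " "))
  map <- data.frame(chrom = km[, 1], pos = as.integer(km[, 2]), strand = "+",
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]; rownames(map) <- NULL
  key <- paste(map$chrom, map$pos)
  mk <- function() matrix(0L, nrow(map), length(samples),
                          dimnames = list(NULL, samples))
  bs_c <- mk(); bs_n <- mk(); ox_c <- mk(); ox_n <- mk()
  for (i in seq_along(tabs)) {
    j <- match(paste(tabs[[i]]$bs$chrom, tabs[[i]]$bs$pos), key)
    bs_c[j, i] <- tabs[[i]]$bs$c_count; bs_n[j, i] <- tabs[[i]]$bs$ct_count
    j <- match(paste(tabs[[i]]$ox$chrom, tabs[[i]]$ox$pos), key)
    ox_c[j, i] <- tabs[[i]]$ox$c_count; ox_n[j, i] <- tabs[[i]]$ox$ct_count
  }
  if (is.null(groups) && "group" %in% names(sheet))
    groups <- stats::setNames(sheet$group, samples)
  structure(list(map = map,
                 counts = list(bs_c = bs_c, bs_n = bs_n,
                               ox_c = ox_c, ox_n = ox_n),
                 truth = NULL, groups = groups, regions = NULL,
                 chemistry = NULL, seed = NULL,
                 sample_data = sheet),
            class = "meth_cohort")
}

#' Write a region x sample matrix as TSV
#'
#' @param mat Numeric matrix with region-id rownames and sample colnames.
#' @param path Output path.
#' @export
write_region_matrix <- function(mat, path) {
  utils::write.table(data.frame(region = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region x sample matrix written by [write_region_matrix()]
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_region_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$region
  m
}
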