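#' Gene model for DMR annotation
#'
#' Holds transcript spans and exon intervals (internal 0-based half-open
#' coordinates) from which strand-aware promoter and TTS windows are derived
#' at annotation time.
#'
#' @param transcripts data.frame: tx_id, chrom, start, end, strand.
#' @param exons data.frame: tx_id, chrom, start, end.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(transcripts, exons) {
  stopifnot(all(c("tx_id", "chrom", "start", "end", "strand") %in%
                  names(transcripts)),
            all(c("tx_id", "chrom", "start", "end") %in% names(exons)))
  if (nrow(exons) > 0) {
    tx <- transcripts[match(exons$tx_id, transcripts$tx_id), ]
    if (any(exons$start < tx$start | exons$end > tx$end, na.rm = TRUE))
      stop("exons must lie within their transcript span")
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d transcripts, %d exons on %s\n",
              nrow(x$transcripts), nrow(x$exons),
              paste(unique(x$transcripts$chrom), collapse = ", ")))
  invisible(x)
}

#' Read a gene model from GTF or BED12
#'
#' GTF exon records are grouped by `transcript_id`; BED12 blocks become
#' exons.  Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path File path; format guessed from the extension
#'   (`.gtf`/`.gff`/`.gff3` vs `.bed`).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    txid <- as.character(gr$transcript_id)
    ex <- data.frame(tx_id = txid,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    sp <- split(seq_len(nrow(ex)), ex$tx_id)
    tx <- do.call(rbind, lapply(names(sp), function(id) {
      i <- sp[[id]]
      data.frame(tx_id = id, chrom = ex$chrom[i[1]],
                 start = min(ex$start[i]), end = max(ex$end[i]),
                 strand = as.character(GenomicRanges::strand(gr))[i[1]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    tx <- data.frame(tx_id = if (!is.null(gr$name)) as.character(gr$name) else
                       sprintf("tx%d", seq_along(gr)),
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
    tx$strand[!tx$strand %in% c("+", "-")] <- "+"
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      ex <- do.call(rbind, lapply(seq_along(gr), function(i) {
        b <- bl[[i]]
        data.frame(tx_id = tx$tx_id[i], chrom = tx$chrom[i],
                   start = tx$start[i] + GenomicRanges::start(b) - 1L,
                   end = tx$start[i] + GenomicRanges::end(b),
                   stringsAsFactors = FALSE)
      }))
    } else {
      ex <- data.frame(tx_id = tx$tx_id, chrom = tx$chrom,
                       start = tx$start, end = tx$end)
    }
  }
  gene_model(tx, ex)
}

.gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         strand = strand)
}

#' Annotate DMRs to genomic categories
#'
#' Each DMR's midpoint is assigned exactly one category with precedence
#' promoter > exon > TTS > intron > intergenic.  Promoter and TTS windows
#' are strand-aware: promoter = TSS - `promoter[1]` .. TSS + `promoter[2]`
#' bp; TTS window = TTS - `tts[1]` .. TTS + `tts[2]` bp (defaults 1000/100
#' and 100/1000, HOMER-like).
#'
#' @param dmrs A `dmr_set` or data.frame with chrom, start, end.
#' @param model A [gene_model()].
#' @param promoter,tts Window sizes in bp: `c(upstream, downstream)`.
#' @return `dmrs` with an added `category` factor column.
#' @export
annotate_dmrs <- function(dmrs, model, promoter = c(1000L, 100L),
                          tts = c(100L, 1000L)) {
  lev <- c("promoter", "exon", "TTS", "intron", "intergenic")
  if (nrow(dmrs) == 0L) {
    dmrs$category <- factor(character(), levels = lev)
    return(dmrs)
  }
  mid <- floor((dmrs$start + dmrs$end) / 2)
  if (nrow(model$transcripts) == 0L) {
    warning("empty gene model: all DMRs annotated as intergenic")
    dmrs$category <- factor(rep("intergenic", nrow(dmrs)), levels = lev)
    return(dmrs)
  }
  pts <- .gr0(dmrs$chrom, mid, mid + 1L)
  tx <- model$transcripts
  tx_gr <- .gr0(tx$chrom, tx$start, tx$end, tx$strand)
  prom_gr <- GenomicRanges::promoters(tx_gr, upstream = promoter[1],
                                      downstream = promoter[2])
  tts_pt <- GenomicRanges::resize(tx_gr, width = 1L, fix = "end")
  tts_gr <- GenomicRanges::promoters(tts_pt, upstream = tts[1],
                                     downstream = tts[2])
  ex_gr <- .gr0(model$exons$chrom, model$exons$start, model$exons$end)
  # seqlevels may legitimately differ (DMRs on gene-free chromosomes)
  ov <- function(gr) suppressWarnings(
    IRanges::overlapsAny(pts, gr, ignore.strand = TRUE))
  cat_v <- rep("intergenic", nrow(dmrs))
  cat_v[ov(tx_gr)] <- "intron"
  cat_v[ov(tts_gr)] <- "TTS"
  cat_v[ov(ex_gr)] <- "exon"
  cat_v[ov(prom_gr)] <- "promoter"
  dmrs$category <- factor(cat_v, levels = lev)
  dmrs
}

#' Category x direction DMR counts
#'
#' Tabulates annotated DMRs by genomic category and hyper/hypo direction,
#' the standard landscape summary for a DMR family.
#'
#' @param dmrs Annotated DMRs (need `category`; `direction` defaults to
#'   "hyper" if absent).
#' @param significant_only Count only significant DMRs (default TRUE when a
#'   `significant` column is present).
#' @return A `table` (category x direction) whose entries sum to the number
#'   of counted DMRs.
#' @export
category_counts <- function(dmrs, significant_only = !is.null(dmrs$significant)) {
  lev <- c("promoter", "exon", "TTS", "intron", "intergenic")
  d <- as.data.frame(dmrs)
  if (significant_only && !is.null(d$significant))
    d <- d[d$significant, , drop = FALSE]
  dir <- if (is.null(d$direction)) rep("hyper", nrow(d)) else d$direction
  table(category = factor(d$category, levels = lev),
        direction = factor(dir, levels = c("hyper", "hypo")))
}
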