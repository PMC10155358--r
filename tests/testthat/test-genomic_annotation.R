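# Constructed fixture covering all precedence collisions:
#   tx A (+): span 5000-9000, exons 5000-5400 and 8600-9000
#   tx B (+): nested, span 6000-8000, exon 6000-8000 (promoter overlaps A's intron)
fixture_model <- function() {
  tx <- data.frame(tx_id = c("A", "B"), chrom = "chr1",
                   start = c(5000L, 6000L), end = c(9000L, 8000L),
                   strand = "+")
  ex <- data.frame(tx_id = c("A", "A", "B"), chrom = "chr1",
                   start = c(5000L, 8600L, 6000L),
                   end = c(5400L, 9000L, 8000L))
  gene_model(tx, ex)
}

dmr_at <- function(mid, chrom = "chr1") {
  data.frame(chrom = chrom, start = mid - 10L, end = mid + 10L,
             direction = "hyper")
}

test_that("midpoint annotation follows promoter > exon > TTS > intron precedence", {
  gm <- fixture_model()
  # promoter window of A (TSS 5000) also overlaps exon 1 -> promoter wins
  expect_equal(as.character(annotate_dmrs(dmr_at(5050L), gm)$category),
               "promoter")
  # intron of A but promoter of nested B -> promoter wins
  expect_equal(as.character(annotate_dmrs(dmr_at(5600L), gm)$category),
               "promoter")
  # inside exon of B (and intron of A) -> exon
  expect_equal(as.character(annotate_dmrs(dmr_at(7000L), gm)$category),
               "exon")
  # just past B's end: TTS window of B, intron of A -> TTS
  expect_equal(as.character(annotate_dmrs(dmr_at(8300L), gm)$category),
               "TTS")
  # inside A's span, outside exons/windows -> intron
  expect_equal(as.character(annotate_dmrs(dmr_at(4200L), gm)$category),
               "promoter")  # still in A's upstream promoter window
  expect_equal(as.character(annotate_dmrs(dmr_at(3500L), gm)$category),
               "intergenic")
  # no genes on this chromosome -> intergenic
  expect_equal(as.character(annotate_dmrs(dmr_at(5050L, "chr9"), gm)$category),
               "intergenic")
})

test_that("every DMR gets exactly one category and counts sum to N", {
  gm <- fixture_model()
  set.seed(4)
  mids <- as.integer(runif(200, 3000, 10000))
  dmrs <- data.frame(chrom = "chr1", start = mids - 5L, end = mids + 5L,
                     direction = sample(c("hyper", "hypo"), 200, TRUE))
  ann <- annotate_dmrs(dmrs, gm)
  expect_false(anyNA(ann$category))
  expect_equal(length(ann$category), 200)
  cc <- category_counts(ann)
  expect_equal(sum(cc), 200)
  expect_equal(unname(rowSums(cc)["intergenic"]) > 0, TRUE)
})

test_that("annotation is invariant under strand mirroring of the model", {
  gm <- fixture_model()
  L <- 20000L
  tx_m <- gm$transcripts
  ex_m <- gm$exons
  tx_m[, c("start", "end")] <- cbind(L - tx_m$end, L - tx_m$start)
  ex_m[, c("start", "end")] <- cbind(L - ex_m$end, L - ex_m$start)
  tx_m$strand <- "-"
  gm_m <- gene_model(tx_m, ex_m)
  mids <- seq(3000L, 10000L, by = 37L)
  fwd <- annotate_dmrs(data.frame(chrom = "chr1", start = mids - 5L,
                                  end = mids + 5L), gm)
  rev_mids <- L - mids
  rev <- annotate_dmrs(data.frame(chrom = "chr1", start = rev_mids - 5L,
                                  end = rev_mids + 5L), gm_m)
  expect_equal(as.character(rev$category), as.character(fwd$category))
})

test_that("empty gene model annotates everything intergenic with a warning", {
  gm0 <- gene_model(data.frame(tx_id = character(), chrom = character(),
                               start = integer(), end = integer(),
                               strand = character()),
                    data.frame(tx_id = character(), chrom = character(),
                               start = integer(), end = integer()))
  expect_warning(ann <- annotate_dmrs(dmr_at(100L), gm0), "intergenic")
  expect_equal(as.character(ann$category), "intergenic")
  cc <- category_counts(data.frame(category = factor(), direction = character()))
  expect_equal(sum(cc), 0)
})

test_that("DMRs planted inside promoters annotate 100% promoter", {
  gm <- fixture_model()
  dmrs <- do.call(rbind, lapply(c(4300L, 4800L, 5050L), dmr_at))
  ann <- annotate_dmrs(dmrs, gm)
  expect_true(all(ann$category == "promoter"))
  cc <- category_counts(ann)
  expect_equal(unname(cc["promoter", "hyper"]), 3L)
})

test_that("gene models read from GTF and BED12 agree with the constructor", {
  gm <- fixture_model()
  # GTF (1-based inclusive)
  gtf <- tempfile(fileext = ".gtf")
  ex <- gm$exons
  writeLines(sprintf(
    'chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "g"; transcript_id "%s";',
    ex$start + 1L, ex$end,
    gm$transcripts$strand[match(ex$tx_id, gm$transcripts$tx_id)], ex$tx_id),
    gtf)
  gm_gtf <- read_gene_model(gtf)
  o <- order(gm_gtf$transcripts$tx_id)
  expect_equal(gm_gtf$transcripts[o, c("tx_id", "start", "end", "strand")],
               gm$transcripts[, c("tx_id", "start", "end", "strand")],
               ignore_attr = TRUE)
  # BED12 with exon blocks
  bed <- tempfile(fileext = ".bed")
  writeLines(c(paste("chr1", 5000, 9000, "A", 0, "+", 5000, 9000, "0",
                     2, "400,400,", "0,3600,", sep = "\t"),
               paste("chr1", 6000, 8000, "B", 0, "+", 6000, 8000, "0",
                     1, "2000,", "0,", sep = "\t")), bed)
  gm_bed <- read_gene_model(bed)
  expect_equal(gm_bed$transcripts[, c("tx_id", "start", "end", "strand")],
               gm$transcripts[, c("tx_id", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(gm_bed$exons[, c("start", "end")], gm$exons[, c("start", "end")],
               ignore_attr = TRUE)
})

test_that("exons outside the transcript span are rejected", {
  expect_error(gene_model(data.frame(tx_id = "A", chrom = "chr1", start = 100L,
                                     end = 200L, strand = "+"),
                          data.frame(tx_id = "A", chrom = "chr1", start = 50L,
                                     end = 150L)),
               "within")
})
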