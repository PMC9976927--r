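test_that("single-exon non-coding transcript is all 5' region", {
  tx <- make_tx("nc1", start = 10L, end = 110L, biotype = "lincRNA")
  rs <- derive_regions(tx)
  expect_equal(as.data.frame(rs$five_prime),
               data.frame(start = 10L, end = 110L))
  expect_equal(nrow(rs$coding_exons), 0L)
  expect_equal(nrow(rs$introns), 0L)
  expect_equal(nrow(rs$three_prime), 0L)
})

test_that("two-exon transcript with CDS inside exon 2 partitions as expected", {
  ex <- data.table(start = c(0L, 200L), end = c(100L, 400L))
  tx <- make_tx("t1", start = 0L, end = 400L, exons = ex,
                cds = c(250L, 350L))
  rs <- derive_regions(tx)
  expect_equal(as.data.frame(rs$introns), data.frame(start = 100L, end = 200L))
  expect_equal(as.data.frame(rs$five_prime),
               data.frame(start = c(0L, 200L), end = c(100L, 250L)))
  expect_equal(as.data.frame(rs$coding_exons),
               data.frame(start = 250L, end = 350L))
  expect_equal(as.data.frame(rs$three_prime),
               data.frame(start = 350L, end = 400L))
  # minus-strand mirror: 5' and 3' swap
  txm <- make_tx("t2", strand = "-", start = 0L, end = 400L, exons = ex,
                 cds = c(250L, 350L))
  rsm <- derive_regions(txm)
  expect_equal(as.data.frame(rsm$three_prime),
               as.data.frame(rs$five_prime))
  expect_equal(as.data.frame(rsm$five_prime),
               as.data.frame(rs$three_prime))
  expect_equal(as.data.frame(rsm$coding_exons),
               as.data.frame(rs$coding_exons))
})

test_that("region derivation errors on a CDS outside the exon union", {
  tx <- make_tx("t1", start = 0L, end = 400L,
                exons = data.table(start = c(0L, 200L), end = c(100L, 400L)))
  expect_error(derive_regions(tx, cds_span = c(120L, 180L)),
               "exon union")
  expect_error(derive_regions(tx, cds_span = c(-5L, 50L)), "span")
})

test_that("regions partition the span: per-base oracle over random transcripts", {
  set.seed(42)
  for (rep in 1:60) {
    n_ex <- sample(1:4, 1L)
    bounds <- sort(sample(0:300, 2L * n_ex))
    ex <- data.table(start = bounds[seq(1, 2 * n_ex, 2)],
                     end = bounds[seq(2, 2 * n_ex, 2)])
    ex <- ex[start < end]
    if (nrow(ex) == 0L) next
    span <- c(min(ex$start), max(ex$end))
    strand <- sample(c("+", "-"), 1L)
    exonic <- unlist(lapply(seq_len(nrow(ex)),
                            function(j) ex$start[j]:(ex$end[j] - 1L)))
    cds <- if (runif(1) < 0.7 && length(exonic) > 2L) {
      cc <- sort(sample(exonic, 2L)); c(cc[1L], cc[2L] + 1L)
    } else c(NA, NA)
    tx <- make_tx("t", strand = strand, start = span[1L], end = span[2L],
                  exons = ex, cds = cds)
    rs <- derive_regions(tx)
    got <- expand_regions(rs, tx)
    expect_false(anyNA(got)) # regions cover the span exactly
    expect_equal(unname(got), unname(oracle_region_labels(tx)))
    # bulk table agrees with the per-transcript route
    tab <- derive_regions_table(tx)
    expanded <- rep(tab$region, tab$end - tab$start)
    names(expanded) <- unlist(lapply(seq_len(nrow(tab)),
                                     function(j) tab$start[j]:(tab$end[j] - 1L)))
    expect_equal(expanded[order(as.integer(names(expanded)))],
                 got[order(as.integer(names(got)))],
                 ignore_attr = TRUE)
  }
})

test_that("high-confidence filter keeps flagged or listed transcripts in order", {
  txs <- rbind(make_tx("a", refseq = FALSE), make_tx("b", refseq = TRUE),
               make_tx("c", refseq = FALSE))
  expect_equal(nrow(filter_high_confidence(txs[refseq_supported == FALSE])), 0L)
  expect_equal(filter_high_confidence(txs)$transcript_id, "b")
  expect_equal(filter_high_confidence(txs, refseq_ids = c("a", "c"))$transcript_id,
               c("a", "b", "c"))
})

test_that("expression filter requires both replicates positive and attaches log10 mean", {
  txs <- rbind(make_tx("a"), make_tx("b"), make_tx("c"))
  expr <- data.table(transcript_id = c("a", "b"),
                     fpkm_rep1 = c(1, 2), fpkm_rep2 = c(0, 2))
  out <- filter_expressed(txs, expr)
  expect_equal(out$transcript_id, "b") # (1, 0) excluded; "c" has no record
  expect_equal(out$log10_fpkm, log10(2))
})

test_that("expression and confidence filters are idempotent and commute", {
  b <- cached_bundle()
  txs <- b$internals$ann$transcripts[biotype == "protein_coding"]
  expr <- b$internals$signals$expression
  f1 <- filter_expressed(filter_high_confidence(txs), expr)
  f2 <- filter_high_confidence(filter_expressed(txs, expr))
  expect_equal(f1$transcript_id, f2$transcript_id)
  expect_equal(filter_high_confidence(f1)$transcript_id, f1$transcript_id)
})

test_that("CTSS clustering merges by gap, drops sub-threshold positions, boundary is >=", {
  ctss <- data.table(chrom = "chr1",
                     position = c(100L, 105L, 300L),
                     strand = "+", tpm = c(5, 3, 0.05))
  cl <- cluster_ctss(ctss, tpm_threshold = 0.1, max_gap = 20L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_pos, 100L)
  expect_equal(cl$end_pos, 105L)
  expect_equal(cl$dominant_pos, 100L)
  expect_equal(cl$width, 6L)
  # empty input
  expect_equal(nrow(cluster_ctss(ctss[0L])), 0L)
  # a 0.09 singleton is excluded, a 0.1 singleton retained
  s <- data.table(chrom = "chr1", position = c(10L, 500L), strand = "+",
                  tpm = c(0.09, 0.1))
  cl2 <- cluster_ctss(s)
  expect_equal(cl2$dominant_pos, 500L)
  expect_error(cluster_ctss(data.table(chrom = "a", position = 1L,
                                       strand = "+", tpm = -1)),
               "negative")
})

test_that("dominant-position ties go to the most 5' position in transcription direction", {
  ctss <- data.table(chrom = "chr1", position = c(100L, 103L),
                     strand = "+", tpm = c(2, 2))
  expect_equal(cluster_ctss(ctss)$dominant_pos, 100L)
  ctss[, strand := "-"]
  expect_equal(cluster_ctss(ctss)$dominant_pos, 103L)
})

test_that("CTSS clusters match the linear-scan oracle and are maximal on random tables", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(5:60, 1L)
    ctss <- data.table(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      position = sample(0:400, n),
      strand = sample(c("+", "-"), n, TRUE),
      tpm = round(runif(n, 0, 2), 2))
    ctss <- unique(ctss, by = c("chrom", "position", "strand"))
    gap <- sample(c(5L, 20L), 1L)
    got <- cluster_ctss(ctss, 0.1, gap)
    exp <- oracle_cluster_ctss(as.data.frame(ctss), 0.1, gap)
    if (is.null(exp)) { expect_equal(nrow(got), 0L); next }
    setorder(got, chrom, strand, start_pos)
    exp <- exp[order(exp$chrom, exp$strand, exp$start_pos), ]
    expect_equal(nrow(got), nrow(exp))
    expect_equal(got$dominant_pos, exp$dominant_pos)
    expect_equal(got$width, exp$width)
    expect_equal(got$total_tpm, exp$total_tpm)
    # maximality: consecutive clusters on one chrom/strand exceed the gap
    for (g in split(got, by = c("chrom", "strand"))) {
      if (nrow(g) < 2L) next
      setorder(g, start_pos)
      expect_true(all(g$start_pos[-1L] - g$end_pos[-nrow(g)] > gap))
    }
  }
})

test_that("dominant-CTSS filter matches TSS exactly (tolerance 0) and attaches the cluster", {
  txs <- rbind(make_tx("a", start = 100L, end = 300L),
               make_tx("b", start = 150L, end = 350L),
               make_tx("c", strand = "-", start = 400L, end = 600L))
  clusters <- cluster_ctss(data.table(
    chrom = "chr1", position = c(100L, 101L, 151L, 599L),
    strand = c("+", "+", "+", "-"), tpm = c(5, 1, 2, 4)))
  out <- filter_by_dominant_ctss(txs, clusters)
  expect_setequal(out$transcript_id, c("a", "c")) # b is 1 bp off
  expect_equal(out[transcript_id == "a"]$tss_cluster_width, 2L)
  out1 <- filter_by_dominant_ctss(txs, clusters, tolerance = 1L)
  expect_setequal(out1$transcript_id, c("a", "b", "c"))
})

test_that("CAGE replicate aggregation picks the most correlated pair and converts to TPM", {
  base <- data.table(chrom = "chr1", position = 1:20, strand = "+")
  r1 <- copy(base)[, count := 1:20]
  r2 <- copy(base)[, count := 1:20 + rpois(20, 1)]
  r3 <- copy(base)[, count := sample(1:20)]
  agg <- aggregate_cage_replicates(list(r1, r2, r3))
  expect_equal(sum(agg$tpm), 1e6)
  # aggregate equals the r1+r2 sum, i.e. the correlated pair was chosen
  expect_equal(agg$tpm, (r1$count + r2$count) / sum(r1$count + r2$count) * 1e6)
})
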