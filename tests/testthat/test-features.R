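test_that("feature column names parse back to their components (bijection)", {
  names <- c("chip.RBFOX2.5prime", "clip.U2AF2.intron",
             "clip.F01.codingexon.Proximal.ncRNA.2",
             "chip.CTCF.3prime.Proximal.ncRNA.1", "tx.len")
  p <- parse_feature_name(names)
  expect_equal(p$assay, c("chip", "clip", "clip", "chip", NA))
  expect_equal(p$factor_name, c("RBFOX2", "U2AF2", "F01", "CTCF", NA))
  expect_equal(p$region, c("5prime", "intron", "codingexon", "3prime", NA))
  expect_equal(p$rank, c(NA, NA, 2L, 1L, NA))
  # reconstruct the names from the parse
  b <- p[!is.na(assay)]
  expect_equal(with(b, pausescape:::binding_feature_name(assay, factor_name,
                                                         region, rank)),
               names[1:4])
  # the source's misspelling is accepted as an alias
  p2 <- parse_feature_name("clip.RBFOX2.5prime.Proxmial.ncRNA.2")
  expect_equal(p2$rank, 2L)
  expect_equal(p2$factor_name, "RBFOX2")
})

test_that("binding flags: no peaks -> all zero; region containment and boundary spanning", {
  tx <- make_tx("t1", start = 0L, end = 400L,
                exons = data.table(start = c(0L, 200L), end = c(100L, 400L)),
                cds = c(250L, 350L))
  regions <- derive_regions_table(tx)
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      factor_name = character(), assay = character())
  X0 <- encode_binding_features(regions, empty, "t1",
                                factors = data.table(factor_name = "F1",
                                                     assay = "chip"))
  expect_true(all(X0 == 0L))
  # peak inside the intron (100, 400 gap is 100-200)
  p1 <- data.table(chrom = "chr1", start = 120L, end = 150L, strand = ".",
                   factor_name = "F1", assay = "chip")
  X1 <- encode_binding_features(regions, p1, "t1")
  expect_equal(sum(X1), 1L)
  expect_equal(unname(X1[1L, "chip.F1.intron"]), 1L)
  # peak spanning the exon/intron boundary sets both flags
  p2 <- data.table(chrom = "chr1", start = 90L, end = 110L, strand = ".",
                   factor_name = "F1", assay = "chip")
  X2 <- encode_binding_features(regions, p2, "t1")
  expect_equal(unname(X2[1L, "chip.F1.intron"]), 1L)
  expect_equal(unname(X2[1L, "chip.F1.5prime"]), 1L)
})

test_that("clip flags require strand agreement; chip flags ignore strand", {
  tx <- make_tx("t1", strand = "-", start = 0L, end = 100L)
  regions <- derive_regions_table(tx)
  p <- data.table(chrom = "chr1", start = 10L, end = 20L,
                  strand = c("+", "-"), factor_name = c("A", "A"),
                  assay = c("clip", "clip"))
  X <- encode_binding_features(regions, p[1L], "t1")
  expect_equal(sum(X), 0L) # opposite strand
  X2 <- encode_binding_features(regions, p[2L], "t1")
  expect_equal(sum(X2), 1L)
  pc <- copy(p[1L])[, `:=`(assay = "chip", strand = ".")]
  X3 <- encode_binding_features(regions, pc, "t1")
  expect_equal(sum(X3), 1L)
})

test_that("binding encoding equals the O(n*m) overlap scan on random fixtures", {
  set.seed(9)
  for (rep in 1:12) {
    txs <- rbindlist(lapply(1:6, function(i) {
      s <- (i - 1L) * 400L
      make_tx(paste0("t", i), strand = sample(c("+", "-"), 1L),
              start = s, end = s + 350L,
              exons = data.table(start = c(s, s + 150L),
                                 end = c(s + 100L, s + 350L)),
              cds = c(s + 50L, s + 250L))
    }))
    regions <- derive_regions_table(txs)
    peaks <- data.table(
      chrom = "chr1",
      start = sample(0:2300, 40L, TRUE),
      strand = sample(c("+", "-", "."), 40L, TRUE),
      factor_name = sample(c("F1", "F2"), 40L, TRUE),
      assay = sample(c("chip", "clip"), 40L, TRUE))
    peaks[, end := start + sample(5:120, 40L, TRUE)]
    peaks[assay == "chip", strand := "."]
    X <- encode_binding_features(regions, peaks, txs$transcript_id)
    meta <- parse_feature_name(colnames(X))
    for (j in seq_len(ncol(X))) {
      for (i in seq_len(nrow(X))) {
        riv <- regions[transcript_id == txs$transcript_id[i] &
                         region == meta$region[j]]
        pk <- peaks[factor_name == meta$factor_name[j] &
                      assay == meta$assay[j]]
        expect_equal(X[i, j],
                     oracle_binding_flag(riv, pk,
                                         stranded = meta$assay[j] == "clip"),
                     info = sprintf("rep %d tx %d col %s", rep, i,
                                    colnames(X)[j]))
      }
    }
  }
})

test_that("proximal ncRNA features rank the two nearest ncRNAs with a deterministic tie rule", {
  txs <- make_tx("t1", start = 1000L, end = 1400L)
  ncrnas <- rbind(
    make_tx("n_far", start = 4000L, end = 4200L, biotype = "lincRNA",
            cds = c(NA, NA)),
    make_tx("n_near", start = 1500L, end = 1700L, biotype = "snRNA",
            cds = c(NA, NA)),
    make_tx("n_mid", strand = "-", start = 200L, end = 400L,
            biotype = "snoRNA", cds = c(NA, NA)))
  peaks <- data.table(
    chrom = "chr1",
    start = c(1550L, 250L, 4050L), end = c(1580L, 280L, 4080L),
    strand = c("+", "-", "+"),
    factor_name = c("A", "A", "A"), assay = "clip")
  X <- proximal_ncrna_features(txs, ncrnas, peaks, k = 2L)
  # nearest: n_near (TSS 1500, d 500), then n_mid (TSS 399, d 601)
  expect_equal(unname(X[1L, "clip.A.5prime.Proximal.ncRNA.1"]), 1L)
  expect_equal(unname(X[1L, "clip.A.5prime.Proximal.ncRNA.2"]), 1L)
  # equidistant pair: smaller TSS coordinate wins rank 1
  nc_tie <- rbind(
    make_tx("left", start = 500L, end = 700L, biotype = "snRNA"),
    make_tx("right", start = 1500L, end = 1700L, biotype = "snRNA"))
  pk <- data.table(chrom = "chr1", start = c(510L), end = c(540L),
                   strand = "+", factor_name = "A", assay = "clip")
  Xt <- proximal_ncrna_features(make_tx("t", start = 1000L, end = 1200L),
                                nc_tie, pk, k = 2L)
  expect_equal(unname(Xt[1L, "clip.A.5prime.Proximal.ncRNA.1"]), 1L)
  # POLR2 factors are excluded from proximal-ncRNA features
  pk2 <- copy(pk)[, factor_name := "POLR2A"]
  expect_equal(ncol(proximal_ncrna_features(make_tx("t", start = 1000L,
                                                    end = 1200L),
                                            nc_tie, pk2)), 0L)
})

test_that("proximal ncRNA selection matches an exhaustive nearest-neighbour oracle", {
  b <- cached_bundle()
  ann <- b$internals$ann
  txs <- head(ann$transcripts[biotype == "protein_coding"], 40L)
  ncs <- ann$transcripts[biotype != "protein_coding"]
  peaks <- b$internals$planted$peaks[assay == "clip"]
  X <- proximal_ncrna_features(txs, ncs, peaks, k = 2L)
  nc_regions <- derive_regions_table(ncs)
  nc_flags <- encode_binding_features(nc_regions, peaks[!grepl("^POLR2", factor_name)],
                                      ncs$transcript_id)
  nc_flags <- nc_flags[, colSums(nc_flags) > 0, drop = FALSE]
  tssn <- ifelse(ncs$strand == "+", ncs$start, ncs$end - 1L)
  for (i in seq_len(nrow(txs))) {
    tss <- if (txs$strand[i] == "+") txs$start[i] else txs$end[i] - 1L
    cand <- which(ncs$chrom == txs$chrom[i])
    ord <- cand[order(abs(tssn[cand] - tss), tssn[cand])]
    sel <- head(ord, 2L)
    for (r in seq_along(sel)) {
      want <- nc_flags[sel[r], ]
      got <- X[i, paste0(colnames(nc_flags), ".Proximal.ncRNA.", r)]
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("CpG features pick the nearest island with deterministic ties and a no-island cap", {
  islands <- data.table(chrom = "chr1",
                        start = c(100L, 900L), end = c(200L, 1000L),
                        length = c(100L, 100L), cpg_count = c(10L, 20L),
                        percent_cg = c(60, 70), percent_cpg = c(10, 15),
                        obs_exp_ratio = c(0.7, 0.9))
  # TSS inside island 1 -> distance 0
  X <- cpg_features(make_tx("a", start = 150L, end = 400L), islands)
  expect_equal(unname(X[1L, "cpg.island.dist"]), 0)
  expect_equal(unname(X[1L, "cpg.island.count"]), 10)
  # equidistant -> smaller-coordinate island
  X2 <- cpg_features(make_tx("b", start = 549L, end = 700L), islands)
  expect_equal(unname(X2[1L, "cpg.island.count"]), 10)
  # no island on the chromosome -> capped distance, zeros elsewhere
  X3 <- cpg_features(make_tx("c", chrom = "chr9", start = 0L, end = 100L),
                     islands, distance_cap = 123)
  expect_equal(unname(X3[1L, ]), c(123, 0, 0, 0, 0, 0))
  # linear-scan oracle on random layouts
  set.seed(21)
  isl <- data.table(chrom = "chr1", start = sort(sample(0:5000, 8L)))
  isl[, end := start + 50L]
  isl[, `:=`(length = 50L, cpg_count = sample(1:30, 8L), percent_cg = 60,
             percent_cpg = 10, obs_exp_ratio = 0.8)]
  for (rep in 1:30) {
    s <- sample(0:5000, 1L)
    tx <- make_tx("t", start = s, end = s + 10L)
    d <- ifelse(s >= isl$start & s < isl$end, 0L,
                pmin(abs(s - isl$start), abs(s - (isl$end - 1L))))
    best <- order(d, isl$start)[1L]
    X <- cpg_features(tx, isl)
    expect_equal(unname(X[1L, "cpg.island.dist"]), as.numeric(d[best]))
    expect_equal(unname(X[1L, "cpg.island.count"]),
                 as.numeric(isl$cpg_count[best]))
  }
})

test_that("annotation features follow their defining formulas", {
  genome <- make_genome(chr1 = strrep("GC", 300),
                        chr2 = random_seq(600, seed = 1))
  # all-GC span: gc fraction 1; single exon: ex.seq = 1, ex.ratio = length
  tx <- make_tx("t1", start = 100L, end = 300L)
  tx[, `:=`(tss_cluster_width = 3L, tss_cluster_start = 100L,
            tss_cluster_end = 102L)]
  X <- annotation_features(tx, genome, housekeeping_genes = "g_t1")
  expect_equal(unname(X[1L, c("tx.len", "tx.gc.seq", "tx.ex.seq",
                              "tx.ex.ratio", "tx.ex.num", "tx.strand",
                              "tx.chr.loc", "tx.loc", "housekeeping",
                              "tx.tss.width", "tx.tss.at.cont")]),
               c(200, 1, 1, 200, 1, 1, 1, 100, 1, 3, 0))
  # two-exon case on chr2 with computed fractions
  ex <- data.table(start = c(100L, 300L), end = c(200L, 360L))
  tx2 <- make_tx("t2", chrom = "chr2", strand = "-", start = 100L,
                 end = 360L, exons = ex, cds = c(120L, 340L))
  tx2[, `:=`(tss_cluster_width = 5L, tss_cluster_start = 355L,
             tss_cluster_end = 359L)]
  X2 <- annotation_features(tx2, genome, character(0))
  expect_equal(unname(X2[1L, "tx.ex.num"]), 2)
  expect_equal(unname(X2[1L, "tx.ex.width"]), 80)
  expect_equal(unname(X2[1L, "tx.ex.seq"]), 160 / 260)
  expect_equal(unname(X2[1L, "tx.ex.ratio"]), 130)
  expect_equal(unname(X2[1L, "tx.strand"]), 0)
  expect_equal(unname(X2[1L, "tx.chr.loc"]), 2)
  s <- get_sequence(genome, "chr2", 100L, 360L)
  expect_equal(unname(X2[1L, "tx.gc.seq"]),
               lengths(regmatches(s, gregexpr("[GC]", s))) / 260)
})

test_that("min-max scaling maps to [0,1], zeroes constants, leaves binaries, and is idempotent", {
  X <- cbind(a = c(0, 5, 10), b = c(1, 1, 1), c = c(0, 1, 0),
             d = c(-2, 0, 2))
  S <- scale_minmax(X)
  expect_equal(S[, "a"], c(0, 0.5, 1))
  expect_equal(S[, "b"], c(0, 0, 0))
  expect_equal(S[, "c"], c(0, 1, 0))
  expect_equal(S[, "d"], c(0, 0.5, 1))
  expect_equal(scale_minmax(S), S)
})

test_that("matrix assembly names columns, stores p_obs, and splits off Pol II columns", {
  ids <- sprintf("t%d", 1:10)
  binding <- matrix(rbinom(40, 1, 0.4), 10, 4,
                    dimnames = list(ids, c("chip.F1.5prime", "chip.F1.intron",
                                           "chip.POLR2A.5prime",
                                           "clip.F2.codingexon")))
  ann <- matrix(c(1:10), 10, 1, dimnames = list(ids, "tx.len"))
  fm <- assemble_matrix(binding, annotation = ann)
  expect_s3_class(fm, "feature_matrix")
  expect_false("chip.POLR2A.5prime" %in% colnames(fm$X))
  expect_equal(colnames(fm$polii), "chip.POLR2A.5prime")
  expect_equal(fm$meta[name == "chip.F1.5prime"]$p_obs,
               mean(binding[, "chip.F1.5prime"]))
  expect_true(all(fm$X >= 0 & fm$X <= 1))
  expect_equal(fm$X[, "tx.len"], setNames((1:10 - 1) / 9, ids))
  dup <- binding; rownames(dup) <- rep("t1", 10)
  expect_error(assemble_matrix(dup, annotation = ann), "duplicate transcript")
})

test_that("synthetic bundle column count matches the combinatorial expectation", {
  b <- cached_bundle()
  run <- cached_run()
  fm <- run$feature_matrix
  pairs <- unique(b$internals$planted$peaks[!grepl("^POLR2", factor_name),
                                            .(factor_name, assay)])
  # direct binding block: 4 region columns per non-PolII factor/assay pair
  n_binding <- sum(fm$meta$kind == "binding" & is.na(fm$meta$rank))
  expect_equal(n_binding, 4L * nrow(pairs))
  # annotation block: 12 transcript features + 6 CpG features
  expect_equal(sum(fm$meta$kind == "annotation"), 18L)
  # Pol II side table holds the two planted POLR2 factors
  expect_equal(ncol(run$feature_matrix$polii), 8L)
})
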