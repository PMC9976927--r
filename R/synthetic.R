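# Seeded synthetic-data generator: emits a complete file bundle (genome,
# GTF, peak BEDs, wiggle coverage pair, expression, CAGE, CpG islands,
# housekeeping list) with planted binding->pausing structure and the
# ground truth needed for end-to-end recovery testing.

#' Synthetic-bundle generator configuration
#'
#' Defaults define the standard study conditions used throughout the
#' package's recovery experiments: 3000 protein-coding genes, 60 binding
#' factors of which 10 are causal for the pausing index, pause signal
#' concentrated within 1 bp of the TSS, expression anti-correlated with
#' pausing, and noise calibrated so that a regression on the true design
#' explains about 70 percent of the pausing-index variance.
#'
#' @param n_genes protein-coding genes.
#' @param n_ncrnas regular non-coding RNAs (a 7SK gene and two pseudo
#'   copies are always added on top).
#' @param n_chromosomes chromosomes genes are distributed over.
#' @param n_factors binding factors (odd-indexed assayed by ChIP,
#'   even-indexed by eCLIP).
#' @param n_causal factors with non-zero planted effects.
#' @param effect_scale multiplier on planted effect sizes (log2 PI
#'   units).
#' @param n_interactions XOR-type interaction terms between causal
#'   factors (gives tree learners an edge over linear ones, as in real
#'   regulatory logic).
#' @param annotation_effect effect size of the two annotation covariates
#'   (GC content, log length) on the pausing index.
#' @param oracle_r2 target R-squared of a regression on the true design;
#'   the residual noise is calibrated to it.
#' @param pi_baseline mean log2 pausing index.
#' @param p_bind per-factor binding probability range (uniform draw per
#'   factor).
#' @param p_bind_ncrna binding probability of eCLIP factors on regular
#'   ncRNAs.
#' @param n_7sk_binders planted 7SK-binding eCLIP factors.
#' @param expr_intercept,expr_slope,expr_noise expression link:
#'   `log10 FPKM = intercept - slope * (pi - mean) + noise`.
#' @param replicate_noise per-replicate log10 FPKM jitter.
#' @param depth body per-base Poisson rate at FPKM 10.
#' @param tx_len_range,ncrna_len_range transcript length ranges (bp).
#' @param max_exons maximum exon count per coding transcript.
#' @param cpg_fraction fraction of coding TSSs with a planted CpG island.
#' @param housekeeping_fraction fraction of genes flagged housekeeping.
#' @param refseq_fraction fraction of transcripts flagged
#'   RefSeq-supported.
#' @param frac_unexpressed fraction of coding transcripts with a zero
#'   replicate (exercises the expression filter).
#' @param n_zero_signal expressed transcripts left without any coverage.
#' @param n_non_acgt transcripts with a planted non-ACGT base.
#' @param n_shifted_ctss transcripts whose dominant CAGE position is
#'   shifted 1 bp off the annotated TSS.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 3000L, n_ncrnas = 60L,
                             n_chromosomes = 4L, n_factors = 60L,
                             n_causal = 10L, effect_scale = 1,
                             n_interactions = 3L,
                             annotation_effect = 0.25, oracle_r2 = 0.7,
                             pi_baseline = 4, p_bind = c(0.15, 0.45),
                             p_bind_ncrna = 0.2, n_7sk_binders = 5L,
                             expr_intercept = 1, expr_slope = 0.35,
                             expr_noise = 0.25, replicate_noise = 0.08,
                             depth = 0.5, tx_len_range = c(600L, 2500L),
                             ncrna_len_range = c(200L, 400L),
                             max_exons = 6L, cpg_fraction = 0.7,
                             housekeeping_fraction = 0.1,
                             refseq_fraction = 0.95,
                             frac_unexpressed = 0.02,
                             n_zero_signal = 5L, n_non_acgt = 3L,
                             n_shifted_ctss = 4L) {
  stopifnot(n_causal <= n_factors, oracle_r2 > 0, oracle_r2 < 1,
            all(p_bind >= 0 & p_bind <= 1), depth > 0)
  structure(as.list(environment()), class = "generator_config")
}

synthetic_factor_names <- function(cfg) {
  nm <- sprintf("F%02d", seq_len(cfg$n_factors))
  data.table(factor_name = nm,
             assay = rep(c("chip", "clip"), length.out = cfg$n_factors))
}

# random sequence as raw bytes (A=65 C=67 G=71 T=84): fast to generate
# and to patch in place
random_dna_raw <- function(n, gc = 0.45) {
  sample(as.raw(c(65L, 67L, 71L, 84L)), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Layout exons for a coding transcript: k exon / k-1 intron blocks with
# minimum widths, scaled to the span.
layout_exons <- function(len, k) {
  min_block <- 60L
  while (k > 1L && (2L * k - 1L) * min_block > len) k <- k - 1L
  nb <- 2L * k - 1L
  w <- runif(nb)
  w <- pmax(min_block, floor(w / sum(w) * (len - nb * min_block)) + min_block)
  excess <- sum(w) - len
  w[which.max(w)] <- w[which.max(w)] - excess
  starts <- cumsum(c(0L, head(w, -1L)))
  data.table(start = as.integer(starts[seq(1L, nb, 2L)]),
             end = as.integer(starts[seq(1L, nb, 2L)] + w[seq(1L, nb, 2L)]))
}

# genomic position of the b-th exonic base (0-based within transcript
# exon union, genomic order)
exonic_to_genomic <- function(exons, b) {
  widths <- exons$end - exons$start
  cum <- cumsum(widths)
  i <- which(b < cum)[1L]
  offset <- b - c(0L, cum)[i]
  exons$start[i] + offset
}

#' Generate the synthetic annotation layer
#'
#' Lays out non-overlapping protein-coding and non-coding transcripts
#' (including an `RN7SK` gene and two pseudo copies) over random-sequence
#' chromosomes, plants CpG islands at a fraction of coding TSSs,
#' deliberately adds one same-strand overlapping coding pair and a few
#' transcripts with non-ACGT bases (so the exclusion filters are
#' exercised), and samples housekeeping and RefSeq support flags.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; a fixed seed gives a byte-identical bundle.
#' @return List with `genome` (`DNAStringSet`), `transcripts` (coding +
#'   ncRNA table in [read_gtf_transcripts()] layout), `cpg_islands`,
#'   `housekeeping`, and the planted special ids (`overlap_pair`,
#'   `non_acgt`, `sevenk_ids`).
#' @export
generate_annotation <- function(cfg, seed = 1L) {
  set.seed(seed)
  n_special_nc <- 3L # RN7SK + two pseudo copies
  units <- data.table(
    kind = c(rep("coding", cfg$n_genes), rep("ncrna", cfg$n_ncrnas),
             rep("sevenk", n_special_nc)))
  units <- units[sample(.N)]
  units[, chrom := paste0("chr", rep_len(seq_len(cfg$n_chromosomes), .N))]
  setorder(units, chrom)
  units[, len := fifelse(kind == "coding",
                         as.integer(runif(.N, cfg$tx_len_range[1L],
                                          cfg$tx_len_range[2L])),
                         as.integer(runif(.N, cfg$ncrna_len_range[1L],
                                          cfg$ncrna_len_range[2L])))]
  units[, gap := as.integer(runif(.N, 300, 800))]
  units[, start := cumsum(shift(len, fill = 0L) + gap) + 200L, by = chrom]
  units[, end := start + len]
  units[, strand := sample(c("+", "-"), .N, replace = TRUE)]

  ncod <- cfg$n_genes
  units[, id := seq_len(.N)]
  cod <- units[kind == "coding"]
  cod[, transcript_id := sprintf("TX%04d", seq_len(.N))]
  cod[, gene_id := sprintf("G%04d", seq_len(.N))]
  nc <- units[kind != "coding"]
  reg <- which(nc$kind == "ncrna")
  nc[, transcript_id := ""]
  nc[, gene_symbol := ""]
  nc[reg, transcript_id := sprintf("NC%03d", seq_along(reg))]
  nc[reg, gene_symbol := sprintf("NCG%03d", seq_along(reg))]
  sv <- which(nc$kind == "sevenk")
  nc[sv, transcript_id := c("TX7SK", "TX7SKP1", "TX7SKP2")]
  nc[sv, gene_symbol := c("RN7SK", "RN7SKP1", "RN7SKP2")]
  nc[, gene_id := paste0("G", transcript_id)]
  nc_biotypes <- c("lincRNA", "snRNA", "snoRNA", "miRNA", "miscRNA")

  cod_lens <- cod$len; cod_starts <- cod$start
  cod_k <- sample.int(cfg$max_exons, nrow(cod), replace = TRUE)
  exon_lists <- vector("list", nrow(cod))
  cds_s <- integer(nrow(cod)); cds_e <- integer(nrow(cod))
  for (i in seq_len(nrow(cod))) {
    ex <- layout_exons(cod_lens[i], cod_k[i])
    ex[, `:=`(start = start + cod_starts[i], end = end + cod_starts[i])]
    el <- sum(ex$end - ex$start)
    cds_s[i] <- exonic_to_genomic(ex, as.integer(floor(0.2 * el)))
    cds_e[i] <- exonic_to_genomic(ex, as.integer(ceiling(0.8 * el)) - 1L) + 1L
    # exons are kept 5'->3' in transcription order, as the GTF reader does
    if (cod$strand[i] == "-") ex <- ex[rev(seq_len(nrow(ex)))]
    exon_lists[[i]] <- ex
  }
  cod_tx <- data.table(
    transcript_id = cod$transcript_id, gene_id = cod$gene_id,
    gene_symbol = sub("^G", "SYM", cod$gene_id), chrom = cod$chrom,
    strand = cod$strand, start = cod$start, end = cod$end,
    biotype = "protein_coding", refseq_supported = NA,
    cds_start = cds_s, cds_end = cds_e, exons = exon_lists)
  nc_tx <- data.table(
    transcript_id = nc$transcript_id, gene_id = nc$gene_id,
    gene_symbol = nc$gene_symbol, chrom = nc$chrom, strand = nc$strand,
    start = nc$start, end = nc$end,
    biotype = ifelse(nc$kind == "sevenk", "miscRNA",
                     sample(nc_biotypes, nrow(nc), replace = TRUE)),
    refseq_supported = NA, cds_start = NA_integer_, cds_end = NA_integer_,
    exons = lapply(seq_len(nrow(nc)), function(j)
      data.table(start = nc$start[j], end = nc$end[j])))
  txs <- rbind(cod_tx, nc_tx)

  # deliberate same-strand overlapping coding pair at the end of chr1
  chr_ends <- units[, .(end = max(end)), by = chrom]
  base <- chr_ends[chrom == "chr1"]$end + 500L
  ov <- data.table(
    transcript_id = c("TXOVL1", "TXOVL2"),
    gene_id = c("GOVL1", "GOVL2"), gene_symbol = c("SYMOVL1", "SYMOVL2"),
    chrom = "chr1", strand = "+", start = c(base, base + 400L),
    end = c(base + 1200L, base + 1600L), biotype = "protein_coding",
    refseq_supported = NA, cds_start = NA_integer_, cds_end = NA_integer_,
    exons = list(data.table(start = base, end = base + 1200L),
                 data.table(start = base + 400L, end = base + 1600L)))
  ov[, cds_start := c(start[1L] + 200L, start[2L] + 200L)]
  ov[, cds_end := c(end[1L] - 200L, end[2L] - 200L)]
  txs <- rbind(txs, ov)
  coding_ids <- txs[biotype == "protein_coding"]$transcript_id
  txs[, refseq_supported := runif(.N) < cfg$refseq_fraction]
  # overlap pair must survive the confidence filter to reach the overlap rule
  txs[transcript_id %in% c("TXOVL1", "TXOVL2"), refseq_supported := TRUE]

  # genome sequence as raw bytes, with GC-enriched promoter patches
  # (planted CpG islands); converted to strings once at the end
  tssv <- tss_position(txs)
  cod_idx <- which(txs$biotype == "protein_coding" &
                     !txs$transcript_id %in% c("TXOVL1", "TXOVL2"))
  with_island <- sort(sample(cod_idx, round(cfg$cpg_fraction * length(cod_idx))))
  chrom_len <- txs[, .(len = max(end) + 1000L), by = chrom]
  gen_raw <- setNames(lapply(chrom_len$len, random_dna_raw),
                      chrom_len$chrom)
  island_rows <- vector("list", length(with_island))
  for (k in seq_along(with_island)) {
    i <- with_island[k]
    s <- max(0L, tssv[i] - 100L)
    e <- min(length(gen_raw[[txs$chrom[i]]]), tssv[i] + 150L)
    gen_raw[[txs$chrom[i]]][(s + 1L):e] <- random_dna_raw(e - s, gc = 0.72)
    island_rows[[k]] <- data.table(chrom = txs$chrom[i], start = s, end = e)
  }
  islands <- rbindlist(island_rows)

  # plant non-ACGT letters inside a few coding spans
  non_acgt <- sample(setdiff(coding_ids, c("TXOVL1", "TXOVL2")),
                     cfg$n_non_acgt)
  for (id in non_acgt) {
    i <- which(txs$transcript_id == id)
    p <- as.integer(txs$start[i] + (txs$end[i] - txs$start[i]) %/% 2L)
    gen_raw[[txs$chrom[i]]][p + 1L] <- as.raw(78L) # 'N'
  }
  genome <- Biostrings::DNAStringSet(vapply(gen_raw, rawToChar, ""))

  # island descriptors from the actual sequence
  count_in_views <- function(chrom, start, end, fun) {
    out <- numeric(length(chrom))
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      v <- Biostrings::Views(genome[[ch]], start = start[i] + 1L,
                             end = end[i])
      out[i] <- fun(v)
    }
    out
  }
  nC <- count_in_views(islands$chrom, islands$start, islands$end,
                       function(v) Biostrings::letterFrequency(v, "C")[, 1L])
  nG <- count_in_views(islands$chrom, islands$start, islands$end,
                       function(v) Biostrings::letterFrequency(v, "G")[, 1L])
  nCpG <- count_in_views(islands$chrom, islands$start, islands$end,
                         function(v) Biostrings::vcountPattern(
                           "CG", Biostrings::DNAStringSet(v)))
  ilen <- islands$end - islands$start
  islands[, `:=`(length = ilen, cpg_count = as.integer(nCpG),
                 percent_cg = 100 * (nC + nG) / ilen,
                 percent_cpg = 100 * 2 * nCpG / ilen,
                 obs_exp_ratio = fifelse(nC * nG == 0, 0,
                                         nCpG * ilen / (nC * nG)))]

  housekeeping <- sample(txs[biotype == "protein_coding"]$gene_id,
                         round(cfg$housekeeping_fraction * length(coding_ids)))
  list(genome = genome, transcripts = txs,
       cpg_islands = islands, housekeeping = housekeeping,
       overlap_pair = c("TXOVL1", "TXOVL2"), non_acgt = non_acgt,
       sevenk_ids = c("TX7SK", "TX7SKP1", "TX7SKP2"))
}

#' Plant binding sites and design indicators
#'
#' Draws, for every target transcript, factor and existing region, a
#' Bernoulli binding indicator (per-factor probability drawn from
#' `cfg$p_bind`), and places one peak inside the region for each
#' indicator that fires (width at most 80 bp, shrunk to the region when
#' shorter, never dropped). eCLIP factors additionally bind regular
#' ncRNAs at rate `p_bind_ncrna`; designated 7SK-binder factors receive
#' CLIP peaks on the 7SK transcripts (one of them only on the
#' above-median pseudo copy), and one decoy factor binds only the
#' below-median pseudo copy.
#'
#' @param ann output of [generate_annotation()].
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return List with `peaks` (interval table), `X` (binary design matrix
#'   transcripts x `(assay.factor.region)` columns over existing
#'   regions), `factors` (`factor_name`, `assay`), `sevenk_binders`
#'   (planted truth), `sevenk_decoy`.
#' @export
plant_binding_sites <- function(ann, cfg, seed = 1L) {
  set.seed(seed)
  factors <- synthetic_factor_names(cfg)
  txs <- ann$transcripts
  targets <- txs[biotype == "protein_coding" &
                   !transcript_id %in% ann$overlap_pair]
  rt <- derive_regions_table(targets)
  # one carrier piece per (transcript, region) for peak placement
  rt1 <- rt[, .SD[sample(.N, 1L)], by = .(transcript_id, region)]
  regions_all <- c("5prime", "codingexon", "intron", "3prime")
  exists_w <- dcast(rt[, .(w = sum(end - start)),
                       by = .(transcript_id, region)],
                    transcript_id ~ region, value.var = "w", fill = 0L)
  exists_w <- exists_w[match(targets$transcript_id, transcript_id)]
  for (r in setdiff(regions_all, names(exists_w))) exists_w[, (r) := 0L]

  n <- nrow(targets)
  p_f <- runif(cfg$n_factors, cfg$p_bind[1L], cfg$p_bind[2L])
  cols <- character(0); Xl <- list()
  for (f in seq_len(cfg$n_factors)) {
    for (r in regions_all) {
      x <- rbinom(n, 1L, p_f[f]) * as.integer(exists_w[[r]] > 0L)
      nm <- binding_feature_name(factors$assay[f], factors$factor_name[f], r)
      cols <- c(cols, nm); Xl[[nm]] <- x
    }
  }
  X <- do.call(cbind, Xl)
  rownames(X) <- targets$transcript_id

  # peak placement, vectorized over all firing indicators
  long <- as.data.table(which(X == 1L, arr.ind = TRUE))
  long[, transcript_id := rownames(X)[row]]
  pf <- parse_feature_name(colnames(X)) # one row per column
  long[, `:=`(assay = pf$assay[col], factor_name = pf$factor_name[col],
              region = pf$region[col])]
  long <- merge(long, rt1[, .(transcript_id, region, chrom, start, end, strand)],
                by = c("transcript_id", "region"), sort = FALSE)
  long[, pw := end - start]
  long[, w := pmin(80L, pw)]
  long[, off := floor(runif(.N) * (pw - w + 1L))]
  peaks <- long[, .(chrom, start = as.integer(start + off),
                    end = as.integer(start + off + w),
                    strand = fifelse(assay == "chip", ".", strand),
                    factor_name, assay)]

  # ncRNA binding for eCLIP factors (regular ncRNAs only)
  ncs <- txs[!biotype %in% "protein_coding" &
               !transcript_id %in% ann$sevenk_ids]
  clipf <- factors[assay == "clip"]$factor_name
  nb <- CJ(transcript_id = ncs$transcript_id, factor_name = clipf)
  nb <- nb[runif(.N) < cfg$p_bind_ncrna]
  if (nrow(nb)) {
    nb <- merge(nb, ncs[, .(transcript_id, chrom, start, end, strand)],
                by = "transcript_id", sort = FALSE)
    nb[, pw := end - start]
    nb[, w := pmin(60L, pw)]
    nb[, off := floor(runif(.N) * (pw - w + 1L))]
    peaks <- rbind(peaks, nb[, .(chrom, start = as.integer(start + off),
                                 end = as.integer(start + off + w),
                                 strand, factor_name, assay = "clip")])
  }

  # planted 7SK binders: n-1 on the real gene, one only on the
  # above-median pseudo copy; a decoy binds only the below-median copy
  binders <- sample(clipf, cfg$n_7sk_binders)
  decoy <- sample(setdiff(clipf, binders), 1L)
  sevenk <- txs[match(ann$sevenk_ids, transcript_id)]
  place_on <- function(f, tx_row) {
    data.table(chrom = tx_row$chrom,
               start = as.integer(tx_row$start +
                                    floor(runif(1) * (tx_row$end - tx_row$start - 30L))),
               strand = tx_row$strand, factor_name = f, assay = "clip")[
                 , .(chrom, start, end = start + 30L, strand, factor_name, assay)]
  }
  sk_peaks <- rbindlist(c(
    lapply(head(binders, -1L), place_on, tx_row = sevenk[1L]),
    list(place_on(tail(binders, 1L), sevenk[2L]),   # RN7SKP1 (above median)
         place_on(decoy, sevenk[3L]))))             # RN7SKP2 (below median)
  peaks <- rbind(peaks, sk_peaks)
  validate_intervals(peaks)
  list(peaks = peaks, X = X, factors = factors, p_bind = p_f,
       sevenk_binders = sort(binders), sevenk_decoy = decoy)
}

# Planted effect structure on the design: main effects on 2 regions per
# causal factor, XOR interactions between causal-factor pairs, plus two
# annotation covariates. Residual noise is calibrated to cfg$oracle_r2.
plant_effects <- function(ann, planted, cfg, seed = 1L) {
  set.seed(seed)
  X <- planted$X
  factors <- planted$factors
  causal <- sort(sample(factors$factor_name, cfg$n_causal))
  regions_all <- c("5prime", "codingexon", "intron", "3prime")
  betas <- rbindlist(lapply(causal, function(f) {
    a <- factors[factor_name == f]$assay
    rs <- sample(regions_all, 2L)
    data.table(factor_name = f, assay = a, region = rs,
               beta = sample(c(-1, 1), 2L, replace = TRUE) *
                 runif(2L, 0.5, 1) * cfg$effect_scale)
  }))
  betas[, name := binding_feature_name(assay, factor_name, region)]
  lp <- as.vector(X[, betas$name, drop = FALSE] %*% betas$beta)

  inter <- NULL
  if (cfg$n_interactions > 0L && cfg$n_causal >= 2L) {
    pairs <- replicate(cfg$n_interactions, sample(causal, 2L))
    inter <- data.table(f1 = pairs[1L, ], f2 = pairs[2L, ],
                        beta = sample(c(-1, 1), cfg$n_interactions, TRUE) *
                          runif(cfg$n_interactions, 0.6, 1) * cfg$effect_scale)
    for (k in seq_len(nrow(inter))) {
      n1 <- betas[factor_name == inter$f1[k]]$name[1L]
      n2 <- betas[factor_name == inter$f2[k]]$name[1L]
      lp <- lp + inter$beta[k] * as.numeric(xor(X[, n1] > 0, X[, n2] > 0))
    }
  }

  # annotation covariates the models can see (GC content, log length)
  targets <- ann$transcripts[match(rownames(X), transcript_id)]
  gc <- seq_letter_fraction(ann$genome, targets$chrom, targets$start,
                            targets$end, c("G", "C"))
  loglen <- log(targets$end - targets$start)
  zs <- function(v) (v - mean(v)) / sd(v)
  lp <- lp + cfg$annotation_effect * zs(gc) + cfg$annotation_effect * zs(loglen)

  sigma <- sqrt(var(lp) * (1 - cfg$oracle_r2) / cfg$oracle_r2)
  eps <- rnorm(length(lp), 0, sigma)
  y <- cfg$pi_baseline + (lp - mean(lp)) + eps
  names(y) <- rownames(X)
  list(y = y, betas = betas, causal_factors = causal,
       interactions = inter, sigma = sigma)
}

#' Simulate coverage, expression and CAGE signals
#'
#' Expression follows `log10 FPKM = a - b * (pi - mean(pi)) + noise`
#' (pausing suppresses output); the body per-base Poisson rate is
#' proportional to FPKM and the TSS-window rate is the body rate times
#' `2^pi`, concentrated within 1 bp of the TSS. CAGE TPM peaks at each
#' TSS with small satellite positions; replicate FPKMs share a mean.
#'
#' @param ann output of [generate_annotation()].
#' @param effects output of the effect-planting step (`y` per target
#'   transcript).
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return List with `track` ([signal_track()]), `expression`,
#'   `ncrna_expression`, `ctss` tables, `unexpressed`, `zero_signal`,
#'   `shifted_ctss` planted id sets, and `polii_peaks` (POLR2* ChIP
#'   peaks whose occupancy tracks the pausing index).
#' @export
simulate_signals <- function(ann, effects, cfg, seed = 1L) {
  set.seed(seed)
  y <- effects$y
  ids <- names(y)
  txs <- ann$transcripts[match(ids, transcript_id)]
  n <- length(y)

  log10_mean <- cfg$expr_intercept - cfg$expr_slope * (y - mean(y)) +
    rnorm(n, 0, cfg$expr_noise)
  rep1 <- 10^(log10_mean + rnorm(n, 0, cfg$replicate_noise))
  rep2 <- 10^(log10_mean + rnorm(n, 0, cfg$replicate_noise))
  unexpressed <- sample(ids, round(cfg$frac_unexpressed * n))
  rep2[ids %in% unexpressed] <- 0
  # overlap-pair transcripts get expression so they reach the overlap rule
  ovl <- ann$overlap_pair
  expression <- data.table(
    transcript_id = c(ids, ovl),
    fpkm_rep1 = c(rep1, rep(5, length(ovl))),
    fpkm_rep2 = c(rep2, rep(5, length(ovl))))

  ncs <- ann$transcripts[!biotype %in% "protein_coding"]
  nc_fpkm <- 10^rnorm(nrow(ncs), 0.5, 0.4)
  names(nc_fpkm) <- ncs$transcript_id
  qs <- quantile(nc_fpkm, c(0.1, 0.75, 0.98))
  nc_fpkm["TX7SKP2"] <- qs[[1L]] * 0.5 # below median: excluded target
  nc_fpkm["TX7SKP1"] <- qs[[2L]]       # above median: included target
  nc_fpkm["TX7SK"] <- qs[[3L]]
  ncrna_expression <- data.table(
    transcript_id = ncs$transcript_id,
    fpkm_rep1 = nc_fpkm * 10^rnorm(nrow(ncs), 0, cfg$replicate_noise),
    fpkm_rep2 = nc_fpkm * 10^rnorm(nrow(ncs), 0, cfg$replicate_noise))

  zero_signal <- sample(setdiff(setdiff(ids, unexpressed), ann$non_acgt),
                        cfg$n_zero_signal)
  fpkm_mean <- 10^log10_mean
  cov_rows <- vector("list", n + length(ovl))
  simulate_tx <- function(chrom, strand, s, e, tss, lam_body, lam_tss) {
    pos <- s:(e - 1L)
    in_tss <- abs(pos - tss) <= 1L
    lam <- ifelse(in_tss, lam_tss, lam_body)
    cnt <- rpois(length(pos), lam)
    keep <- cnt > 0L
    if (!any(keep)) return(NULL)
    data.table(chrom = chrom, strand = strand, pos = pos[keep],
               value = as.numeric(cnt[keep]))
  }
  tssv <- tss_position(txs)
  for (i in seq_len(n)) {
    if (ids[i] %in% zero_signal) next
    if (ids[i] %in% unexpressed) next
    lam_body <- cfg$depth * fpkm_mean[i] / 10
    cov_rows[[i]] <- simulate_tx(txs$chrom[i], txs$strand[i], txs$start[i],
                                 txs$end[i], tssv[i], lam_body,
                                 lam_body * 2^y[i])
  }
  # overlap pair: plain coverage so they carry signal
  ovt <- ann$transcripts[match(ovl, transcript_id)]
  for (k in seq_along(ovl)) {
    cov_rows[[n + k]] <- simulate_tx(ovt$chrom[k], ovt$strand[k],
                                     ovt$start[k], ovt$end[k],
                                     tss_position(ovt[k]), cfg$depth,
                                     cfg$depth * 2^cfg$pi_baseline)
  }
  # light coverage on expressed ncRNAs
  nc_cov <- lapply(seq_len(nrow(ncs)), function(j) {
    lam <- 0.3
    pos <- ncs$start[j]:(ncs$end[j] - 1L)
    cnt <- rpois(length(pos), lam)
    keep <- cnt > 0L
    if (!any(keep)) return(NULL)
    data.table(chrom = ncs$chrom[j], strand = ncs$strand[j],
               pos = pos[keep], value = as.numeric(cnt[keep]))
  })
  cov <- rbindlist(c(cov_rows, nc_cov))
  cov <- cov[, .(value = sum(value)), by = .(chrom, strand, pos)]
  track <- signal_track(cov, genome_tag = "synthetic")

  # CAGE: dominant TPM peak at each coding TSS plus satellites
  shifted <- sample(setdiff(ids, c(unexpressed, zero_signal)),
                    cfg$n_shifted_ctss)
  dirs <- ifelse(txs$strand == "+", 1L, -1L)
  main_tpm <- rgamma(n, shape = 2, scale = 5) + 1
  main_pos <- tssv + ifelse(ids %in% shifted, dirs, 0L)
  ctss <- rbindlist(list(
    data.table(chrom = txs$chrom, position = main_pos, strand = txs$strand,
               tpm = main_tpm),
    data.table(chrom = txs$chrom, position = tssv + dirs,
               strand = txs$strand, tpm = 0.25 * main_tpm),
    data.table(chrom = txs$chrom, position = tssv + 2L * dirs,
               strand = txs$strand, tpm = 0.1 * main_tpm)))
  ctss <- ctss[position != rep(main_pos, 3L) | tpm == main_tpm]
  # overlap pair gets a clean CAGE peak so it reaches the overlap rule
  ctss <- rbind(ctss,
                data.table(chrom = ovt$chrom, position = tss_position(ovt),
                           strand = ovt$strand, tpm = 5))
  # sub-threshold noise singletons, excluded by clustering
  noise <- data.table(chrom = sample(txs$chrom, 50L, TRUE),
                      position = as.integer(runif(50L, 0, 5e4)),
                      strand = sample(c("+", "-"), 50L, TRUE), tpm = 0.05)
  ctss <- rbind(ctss, noise)
  ctss <- ctss[, .(tpm = sum(tpm)), by = .(chrom, position, strand)]

  # Pol II occupancy tracks the pausing index
  pol_prob <- stats::plogis(1.2 * (y - mean(y)))
  polii_rows <- list()
  for (f in c("POLR2A", "POLR2B")) {
    hit <- which(runif(n) < pol_prob)
    if (length(hit))
      polii_rows[[f]] <- data.table(
        chrom = txs$chrom[hit],
        start = as.integer(pmax(0L, tssv[hit] - 40L)),
        end = as.integer(tssv[hit] + 40L),
        strand = ".", factor_name = f, assay = "chip")
  }
  polii_peaks <- rbindlist(polii_rows)

  list(track = track, expression = expression,
       ncrna_expression = ncrna_expression, ctss = ctss,
       unexpressed = unexpressed, zero_signal = zero_signal,
       shifted_ctss = shifted, polii_peaks = polii_peaks)
}

#' Generate and write a complete synthetic bundle
#'
#' Runs annotation generation, binding-site planting, effect planting
#' and signal simulation under one seed and writes every file in the
#' dialects the package's readers consume: FASTA genome, GTF annotation,
#' per-factor BED peak files, a plus/minus wiggle pair, expression and
#' CAGE TSV tables, CpG-island TSV, housekeeping list and a ground-truth
#' JSON.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created).
#' @param seed integer seed controlling every random draw.
#' @param shared optional internals of a previous bundle (as returned in
#'   `$internals`) to reuse annotation and effect sizes for a second
#'   cell line; `perturb_factors` then names causal factors whose
#'   binding indicators are redrawn (cell-specific binding).
#' @param perturb_factors see `shared`.
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (`y`, `causal_factors`, `betas`, `sevenk_binders`, planted special
#'   ids) and `internals` (annotation, design `X`, peaks, effects) for
#'   in-memory use.
#' @export
simulate_bundle <- function(cfg = generator_config(), dir, seed = 1L,
                            shared = NULL, perturb_factors = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(shared)) {
    ann <- generate_annotation(cfg, seed)
    planted <- plant_binding_sites(ann, cfg, seed + 1L)
    effects <- plant_effects(ann, planted, cfg, seed + 2L)
  } else {
    ann <- shared$ann
    planted <- shared$planted
    effects <- shared$effects
    set.seed(seed + 3L)
    # redraw binding indicators (and peaks) for the perturbed factors
    redraw <- plant_binding_sites(ann, cfg, seed + 4L)
    sel <- parse_feature_name(colnames(planted$X))$factor_name %in%
      perturb_factors
    X <- planted$X
    X[, sel] <- redraw$X[, sel]
    peaks <- rbind(
      planted$peaks[!factor_name %in% perturb_factors],
      redraw$peaks[factor_name %in% perturb_factors])
    planted$X <- X
    planted$peaks <- peaks
    # same effect sizes, fresh residual noise
    set.seed(seed + 5L)
    lp <- as.vector(X[, effects$betas$name, drop = FALSE] %*%
                      effects$betas$beta)
    if (!is.null(effects$interactions)) {
      for (k in seq_len(nrow(effects$interactions))) {
        n1 <- effects$betas[factor_name == effects$interactions$f1[k]]$name[1L]
        n2 <- effects$betas[factor_name == effects$interactions$f2[k]]$name[1L]
        lp <- lp + effects$interactions$beta[k] *
          as.numeric(xor(X[, n1] > 0, X[, n2] > 0))
      }
    }
    lp <- lp + effects$annotation_part
    y <- cfg$pi_baseline + (lp - mean(lp)) +
      rnorm(length(lp), 0, effects$sigma)
    names(y) <- rownames(X)
    effects$y <- y
  }
  # cache the annotation covariate part for cell-pair reuse
  if (is.null(effects$annotation_part)) {
    targets <- ann$transcripts[match(rownames(planted$X), transcript_id)]
    gc <- seq_letter_fraction(ann$genome, targets$chrom, targets$start,
                              targets$end, c("G", "C"))
    loglen <- log(targets$end - targets$start)
    zs <- function(v) (v - mean(v)) / sd(v)
    effects$annotation_part <- cfg$annotation_effect * (zs(gc) + zs(loglen))
  }
  sig <- simulate_signals(ann, effects, cfg, seed + 6L)
  peaks <- rbind(planted$peaks, sig$polii_peaks)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    expression = file.path(dir, "expression.tsv"),
    ncrna_expression = file.path(dir, "ncrna_expression.tsv"),
    ctss = file.path(dir, "ctss.tsv"),
    cpg = file.path(dir, "cpg_islands.tsv"),
    housekeeping = file.path(dir, "housekeeping.txt"),
    wig_plus = file.path(dir, "signal_plus.wig"),
    wig_minus = file.path(dir, "signal_minus.wig"),
    peaks_dir = file.path(dir, "peaks"),
    truth = file.path(dir, "truth.json"))
  write_fasta(ann$genome, paths$genome)
  write_gtf_transcripts(ann$transcripts, paths$gtf)
  fwrite(sig$expression, paths$expression, sep = "\t")
  fwrite(sig$ncrna_expression, paths$ncrna_expression, sep = "\t")
  fwrite(sig$ctss, paths$ctss, sep = "\t")
  fwrite(ann$cpg_islands, paths$cpg, sep = "\t")
  writeLines(ann$housekeeping, paths$housekeeping)
  write_wig_signal(sig$track, paths$wig_plus, paths$wig_minus)
  if (!dir.exists(paths$peaks_dir)) dir.create(paths$peaks_dir)
  for (sp in split(peaks, by = c("assay", "factor_name"))) {
    write_bed_peaks(sp, file.path(paths$peaks_dir,
                                  sprintf("%s_%s.bed", sp$assay[1L],
                                          sp$factor_name[1L])))
  }
  truth <- list(y = as.list(effects$y),
                causal_factors = effects$causal_factors,
                betas = effects$betas[, .(factor_name, assay, region, beta)],
                sigma = effects$sigma,
                sevenk_binders = planted$sevenk_binders,
                sevenk_decoy = planted$sevenk_decoy,
                overlap_pair = ann$overlap_pair,
                non_acgt = ann$non_acgt,
                zero_signal = sig$zero_signal,
                unexpressed = sig$unexpressed,
                shifted_ctss = sig$shifted_ctss,
                seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth,
                 internals = list(ann = ann, planted = planted,
                                  effects = effects, signals = sig)))
}
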