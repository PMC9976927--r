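# Transcripts x features matrix assembly: binary binding flags per
# (assay, factor, region) including the two most TSS-proximal ncRNAs,
# CpG-island features and the annotation/sequence feature block.

POLII_PATTERN <- "^POLR2"

#' Parse a binding feature column name
#'
#' Column names follow `chip.<FACTOR>.<region>` /
#' `clip.<FACTOR>.<region>` and
#' `<assay>.<FACTOR>.<region>.Proximal.ncRNA.<rank>` for proximal-ncRNA
#' features. The misspelling `Proxmial` is accepted as an input alias.
#'
#' @param name character vector of column names.
#' @return `data.table(name, assay, factor_name, region, rank)`; `rank`
#'   is `NA` for direct binding columns, and all fields are `NA` for
#'   annotation columns.
#' @export
parse_feature_name <- function(name) {
  canon <- sub(".Proxmial.ncRNA.", ".Proximal.ncRNA.", name, fixed = TRUE)
  pat <- "^(chip|clip)\\.(.+)\\.(5prime|codingexon|intron|3prime)(\\.Proximal\\.ncRNA\\.([0-9]+))?$"
  ok <- grepl(pat, canon)
  assay <- factor_name <- region <- rep(NA_character_, length(name))
  rank <- rep(NA_integer_, length(name))
  if (any(ok)) {
    assay[ok] <- sub(pat, "\\1", canon[ok])
    factor_name[ok] <- sub(pat, "\\2", canon[ok])
    region[ok] <- sub(pat, "\\3", canon[ok])
    r <- sub(pat, "\\5", canon[ok])
    rank[ok] <- suppressWarnings(as.integer(r))
  }
  data.table(name = name, assay = assay, factor_name = factor_name,
             region = region, rank = rank)
}

binding_feature_name <- function(assay, factor, region, rank = NA_integer_) {
  base <- paste(assay, factor, region, sep = ".")
  rank <- rep_len(rank, length(base))
  ifelse(is.na(rank), base, paste0(base, ".Proximal.ncRNA.", rank))
}

# Overlap join of peaks against a region table; returns unique
# (transcript_id, assay, factor_name, region) hits. ChIP peaks are
# strandless; CLIP peaks require the same strand when stranded.
overlap_hits <- function(regions, peaks) {
  if (nrow(peaks) == 0L || nrow(regions) == 0L)
    return(data.table(transcript_id = character(), assay = character(),
                      factor_name = character(), region = character()))
  p <- as.data.table(peaks)
  r <- as.data.table(regions)
  setkey(r, chrom, start, end)
  ov <- foverlaps(p, r, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  # half-open intervals: foverlaps treats ends as inclusive, so drop
  # zero-width touches
  ov <- ov[i.start < end & start < i.end]
  ov <- ov[assay == "chip" | i.strand == "." | i.strand == strand]
  unique(ov[, .(transcript_id, assay, factor_name, region)])
}

#' Encode binary binding flags per (assay, factor, region)
#'
#' A flag is 1 iff at least one peak overlaps at least 1 bp of any
#' interval of that region; a peak spanning a region boundary sets both
#' flags. CLIP peaks additionally require strand agreement when their
#' strand is declared.
#'
#' @param regions region table ([derive_regions_table()]).
#' @param peaks peak table ([read_bed_peaks()] rows, possibly several
#'   factors/assays bound together).
#' @param transcript_ids row universe; transcripts without hits get
#'   all-zero rows.
#' @param factors optional `data.table(factor_name, assay)` declaring the
#'   column universe; defaults to the pairs present in `peaks`.
#' @return Binary integer matrix, rownames `transcript_ids`, colnames per
#'   [binding_feature_name()] (all 4 regions per factor/assay pair).
#' @export
encode_binding_features <- function(regions, peaks, transcript_ids,
                                    factors = NULL) {
  if (is.null(factors))
    factors <- unique(as.data.table(peaks)[, .(factor_name, assay)])
  regions_all <- c("5prime", "codingexon", "intron", "3prime")
  cols <- factors[rep(seq_len(nrow(factors)), each = 4L)]
  cols[, region := rep(regions_all, nrow(factors))]
  cols[, name := binding_feature_name(assay, factor_name, region)]
  X <- matrix(0L, nrow = length(transcript_ids), ncol = nrow(cols),
              dimnames = list(transcript_ids, cols$name))
  hits <- overlap_hits(regions, peaks)
  if (nrow(hits)) {
    hits[, name := binding_feature_name(assay, factor_name, region)]
    hits <- hits[transcript_id %in% transcript_ids & name %in% cols$name]
    X[cbind(match(hits$transcript_id, transcript_ids),
            match(hits$name, cols$name))] <- 1L
  }
  X
}

#' Binding flags on the two most TSS-proximal non-coding RNAs
#'
#' For each target transcript, selects the `k` non-coding transcripts
#' with smallest TSS-to-TSS distance (any strand or side; ties go to the
#' smaller ncRNA TSS coordinate) and emits region-resolved binding flags
#' of each selected ncRNA, ranked 1..k by proximity. Pol II factors
#' (POLR2*) are excluded. When fewer than `k` ncRNAs share the
#' chromosome, the remaining ranks stay all-zero.
#'
#' @param txs target (protein-coding) transcript table.
#' @param ncrna_txs non-coding transcript table (expressed set).
#' @param peaks peak table.
#' @param k number of proximal ncRNAs (default 2).
#' @return Binary integer matrix with columns
#'   `<assay>.<FACTOR>.<region>.Proximal.ncRNA.<rank>`.
#' @export
proximal_ncrna_features <- function(txs, ncrna_txs, peaks, k = 2L) {
  peaks <- as.data.table(peaks)[!grepl(POLII_PATTERN, factor_name)]
  nc_regions <- derive_regions_table(ncrna_txs)
  nc_flags <- encode_binding_features(nc_regions, peaks,
                                      ncrna_txs$transcript_id)
  # keep only factor/assay pairs with >= 1 ncRNA binding event
  nc_flags <- nc_flags[, colSums(nc_flags) > 0, drop = FALSE]
  if (ncol(nc_flags) == 0L || nrow(ncrna_txs) == 0L)
    return(matrix(0L, nrow = nrow(txs), ncol = 0L,
                  dimnames = list(txs$transcript_id, character(0))))
  cols <- as.vector(outer(colnames(nc_flags), seq_len(k),
                          function(nm, r) paste0(nm, ".Proximal.ncRNA.", r)))
  X <- matrix(0L, nrow = nrow(txs), ncol = length(cols),
              dimnames = list(txs$transcript_id, cols))
  tss_tx <- tss_position(txs)
  tss_nc <- tss_position(ncrna_txs)
  for (i in seq_len(nrow(txs))) {
    on_chr <- which(ncrna_txs$chrom == txs$chrom[i])
    if (length(on_chr) == 0L) next
    d <- abs(tss_nc[on_chr] - tss_tx[i])
    ord <- on_chr[order(d, tss_nc[on_chr])]
    sel <- head(ord, k)
    for (r in seq_along(sel)) {
      flags <- nc_flags[sel[r], ]
      hit <- which(flags > 0)
      if (length(hit))
        X[i, paste0(colnames(nc_flags)[hit], ".Proximal.ncRNA.", r)] <- 1L
    }
  }
  X
}

#' Read a UCSC-style CpG island table
#'
#' @param path TSV with header `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `cpg_count`, `percent_cg`, `percent_cpg`,
#'   `obs_exp_ratio`.
#' @return `data.table` of those columns.
#' @export
read_cpg_islands <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("chrom", "start", "end", "length", "cpg_count", "percent_cg",
            "percent_cpg", "obs_exp_ratio")
  if (!all(need %in% names(dt)))
    stop("CpG island table must have columns: ", paste(need, collapse = ", "))
  dt[, ..need]
}

#' CpG-island features per transcript
#'
#' Finds the island nearest to each transcript's TSS (distance 0 when the
#' TSS lies inside an island; ties go to the smaller-coordinate island)
#' and emits its distance plus five island descriptors.
#'
#' @param txs transcript table.
#' @param islands CpG island table ([read_cpg_islands()]).
#' @param distance_cap distance reported when the chromosome has no
#'   island (other features 0).
#' @return Numeric matrix with columns `cpg.island.dist`,
#'   `cpg.island.length`, `cpg.island.count`, `cpg.island.percent.cg`,
#'   `cpg.island.percent.cpg`, `cpg.island.percent.exp.v.obs`.
#' @export
cpg_features <- function(txs, islands, distance_cap = 1e6) {
  cols <- c("cpg.island.dist", "cpg.island.length", "cpg.island.count",
            "cpg.island.percent.cg", "cpg.island.percent.cpg",
            "cpg.island.percent.exp.v.obs")
  X <- matrix(0, nrow = nrow(txs), ncol = length(cols),
              dimnames = list(txs$transcript_id, cols))
  isl <- as.data.table(islands)
  tssv <- tss_position(txs)
  for (i in seq_len(nrow(txs))) {
    cand <- isl[chrom == txs$chrom[i]]
    if (nrow(cand) == 0L) { X[i, "cpg.island.dist"] <- distance_cap; next }
    tss <- tssv[i]
    d <- ifelse(tss >= cand$start & tss < cand$end, 0L,
                pmin(abs(tss - cand$start), abs(tss - (cand$end - 1L))))
    j <- order(d, cand$start)[1L]
    X[i, ] <- c(d[j], cand$length[j], cand$cpg_count[j],
                cand$percent_cg[j], cand$percent_cpg[j],
                cand$obs_exp_ratio[j])
  }
  X
}

# ordinal chromosome index: chr1..chr22 -> 1..22, chrX -> 23, chrY -> 24,
# anything else after that in name order
chrom_ordinal <- function(chrom) {
  nm <- sub("^chr", "", chrom)
  idx <- suppressWarnings(as.integer(nm))
  idx[nm == "X"] <- 23L
  idx[nm == "Y"] <- 24L
  other <- is.na(idx)
  if (any(other))
    idx[other] <- 24L + as.integer(factor(nm[other], levels = sort(unique(nm[other]))))
  idx
}

#' Gene annotation and sequence-composition features
#'
#' Twelve transcript-level features: length, strand, chromosome index,
#' genomic location, exon count, mean exon width, exon density
#' (length / exon count), exonic-sequence fraction, GC fraction of the
#' whole span, CAGE cluster width, AT fraction of the cluster span, and a
#' housekeeping indicator. Transcripts lacking an attached CAGE cluster
#' get zero TSS-cluster features (with a warning).
#'
#' @param txs transcript table; `tss_cluster_width`/`_start`/`_end` are
#'   used when present ([filter_by_dominant_ctss()]).
#' @param genome `DNAStringSet`.
#' @param housekeeping_genes character set of housekeeping gene ids or
#'   symbols.
#' @return Numeric matrix with columns `tx.len`, `tx.strand`,
#'   `tx.chr.loc`, `tx.loc`, `tx.ex.num`, `tx.ex.width`, `tx.ex.ratio`,
#'   `tx.ex.seq`, `tx.gc.seq`, `tx.tss.width`, `tx.tss.at.cont`,
#'   `housekeeping`.
#' @export
annotation_features <- function(txs, genome, housekeeping_genes = character(0)) {
  n <- nrow(txs)
  len <- txs$end - txs$start
  ex_num <- vapply(txs$exons, nrow, 0L)
  ex_len <- vapply(txs$exons, function(e) sum(e$end - e$start), 0L)
  gc <- seq_letter_fraction(genome, txs$chrom, txs$start, txs$end,
                            c("G", "C"))
  has_cluster <- all(c("tss_cluster_width", "tss_cluster_start",
                       "tss_cluster_end") %in% names(txs))
  if (!has_cluster) {
    warning("no CAGE cluster attached; TSS-cluster features set to 0")
    tss_w <- rep(0, n); tss_at <- rep(0, n)
  } else {
    tss_w <- txs$tss_cluster_width
    tss_at <- seq_letter_fraction(genome, txs$chrom, txs$tss_cluster_start,
                                  txs$tss_cluster_end + 1L, c("A", "T"))
  }
  hk <- as.integer(txs$gene_id %in% housekeeping_genes |
                     txs$gene_symbol %in% housekeeping_genes)
  cbind(tx.len = len,
        tx.strand = as.integer(txs$strand == "+"),
        tx.chr.loc = chrom_ordinal(txs$chrom),
        tx.loc = txs$start,
        tx.ex.num = ex_num,
        tx.ex.width = ex_len / ex_num,
        tx.ex.ratio = len / ex_num,
        tx.ex.seq = ex_len / len,
        tx.gc.seq = gc,
        tx.tss.width = tss_w,
        tx.tss.at.cont = tss_at,
        housekeeping = hk) |>
    (\(m) { rownames(m) <- txs$transcript_id; m })()
}

#' Min-max scale matrix columns to [0, 1]
#'
#' Binary columns are left untouched; constant columns become 0.
#'
#' @param X numeric matrix.
#' @return Scaled matrix; scaling an already-scaled matrix is the
#'   identity.
#' @export
scale_minmax <- function(X) {
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    rng <- range(v)
    if (rng[1] == rng[2]) {        # constant column (even all-ones)
      if (rng[1] != 0) X[, j] <- 0
      next
    }
    if (all(v %in% c(0, 1))) next  # binary columns pass through
    X[, j] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  X
}

#' Assemble the full feature matrix
#'
#' Binds the binding-flag, proximal-ncRNA, CpG and annotation blocks,
#' min-max scales numeric columns, and splits off Pol II (POLR2*)
#' binding columns into a side table (they correlate with the prediction
#' target by construction and are only used by the Pol II-only reference
#' model).
#'
#' @param binding matrix from [encode_binding_features()].
#' @param ncrna matrix from [proximal_ncrna_features()] (or `NULL`).
#' @param cpg matrix from [cpg_features()] (or `NULL`).
#' @param annotation matrix from [annotation_features()] (or `NULL`).
#' @param scale min-max scale numeric columns (default `TRUE`).
#' @return A list of class `feature_matrix`: `X` (numeric matrix), `meta`
#'   (`data.table(name, kind, assay, factor_name, region, rank, p_obs)`
#'   where `p_obs` is the pre-scaling column mean of binding columns) and
#'   `polii` (matrix of excluded POLR2* columns, or `NULL`).
#' @export
assemble_matrix <- function(binding, ncrna = NULL, cpg = NULL,
                            annotation = NULL, scale = TRUE) {
  blocks <- Filter(Negate(is.null), list(binding, ncrna, cpg, annotation))
  ids <- rownames(blocks[[1L]])
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  for (b in blocks) stopifnot(identical(rownames(b), ids))
  X <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(X))) stop("duplicate feature column names")
  meta <- parse_feature_name(colnames(X))
  meta[, kind := ifelse(is.na(assay), "annotation", "binding")]
  meta[, p_obs := ifelse(kind == "binding", colMeans(X), NA_real_)]
  is_polii <- meta$kind == "binding" & grepl(POLII_PATTERN, meta$factor_name)
  polii <- if (any(is_polii)) X[, meta$name[is_polii], drop = FALSE] else NULL
  X <- X[, !is_polii, drop = FALSE]
  meta <- meta[!is_polii]
  if (scale) X <- scale_minmax(X)
  structure(list(X = X, meta = meta, polii = polii),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d transcripts x %d features (%d binding, %d annotation)%s\n",
              nrow(x$X), ncol(x$X), sum(x$meta$kind == "binding"),
              sum(x$meta$kind == "annotation"),
              if (is.null(x$polii)) "" else
                sprintf("; %d Pol II side columns", ncol(x$polii))))
  invisible(x)
}
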