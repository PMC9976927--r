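# Transcript-centric annotation: derived genomic regions (5', coding
# exon, intron, 3'), expression- and CAGE-based transcript filters.

#' Derive 5'/coding-exon/intron/3' regions for one transcript
#'
#' Splits a transcript into four mutually exclusive region classes. The
#' 5' region is the exonic sequence upstream (in transcription direction)
#' of the CDS start, the 3' region the exonic sequence downstream of the
#' CDS end, coding exons the exonic intersection with the CDS span, and
#' introns the span minus all exons. Transcripts without a CDS treat all
#' exonic sequence as 5' region.
#'
#' @param tx a single transcript row (as in [read_gtf_transcripts()]).
#' @param cds_span optional `c(start, end)` 0-based half-open genomic CDS
#'   span; defaults to the transcript's own `cds_start`/`cds_end`.
#' @return A list of interval `data.table`s: `five_prime`, `coding_exons`,
#'   `introns`, `three_prime` (genomic order, 0-based half-open).
#' @export
derive_regions <- function(tx, cds_span = NULL) {
  ex <- as.data.table(tx$exons[[1L]])[order(start)]
  span_s <- tx$start; span_e <- tx$end
  if (is.null(cds_span)) {
    cds_span <- if (!is.na(tx$cds_start)) c(tx$cds_start, tx$cds_end) else NULL
  }
  introns <- gaps_in_span(ex, span_s, span_e)
  empty <- ex[0L, .(start, end)]
  if (is.null(cds_span)) {
    return(list(five_prime = ex[, .(start, end)], coding_exons = empty,
                introns = introns, three_prime = empty))
  }
  cs <- as.integer(cds_span[1L]); ce <- as.integer(cds_span[2L])
  if (cs < span_s || ce > span_e || cs >= ce)
    stop("cds_span outside transcript span")
  if (interval_width(clip_intervals(ex, cs, ce)) == 0L)
    stop("cds_span does not intersect the exon union")
  coding <- clip_intervals(ex, cs, ce)
  upstream <- clip_intervals(ex, span_s, cs)   # genomic-left of CDS
  downstream <- clip_intervals(ex, ce, span_e) # genomic-right of CDS
  if (tx$strand == "-") { tmp <- upstream; upstream <- downstream; downstream <- tmp }
  list(five_prime = upstream, coding_exons = coding,
       introns = introns, three_prime = downstream)
}

#' Region table for many transcripts
#'
#' Vectorized companion of [derive_regions()]: one row per region
#' interval, tagged with transcript id and region class.
#'
#' @param txs transcript table.
#' @return `data.table(transcript_id, region, chrom, start, end, strand)`
#'   with `region` in `{5prime, codingexon, intron, 3prime}`.
#' @export
derive_regions_table <- function(txs) {
  nex <- vapply(txs$exons, nrow, 0L)
  long <- data.table(
    transcript_id = rep(txs$transcript_id, nex),
    chrom = rep(txs$chrom, nex),
    strand = rep(txs$strand, nex),
    cds_s = rep(txs$cds_start, nex),
    cds_e = rep(txs$cds_end, nex),
    es = unlist(lapply(txs$exons, `[[`, "start")),
    ee = unlist(lapply(txs$exons, `[[`, "end")))
  setorder(long, transcript_id, es)
  piece <- function(dt, s, e, region) {
    out <- dt[, .(transcript_id, region = region, chrom,
                  start = pmax(es, s), end = pmin(ee, e), strand)]
    out[start < end]
  }
  has_cds <- !is.na(long$cds_s)
  nc <- long[!has_cds]
  cd <- long[has_cds]
  five_nc <- nc[, .(transcript_id, region = "5prime", chrom,
                    start = es, end = ee, strand)]
  coding <- piece(cd, cd$cds_s, cd$cds_e, "codingexon")
  # genomic-left / genomic-right of CDS; swap labels on the minus strand
  left <- piece(cd, -1L, cd$cds_s, NA_character_)
  right <- piece(cd, cd$cds_e, .Machine$integer.max, NA_character_)
  left[, region := fifelse(strand == "-", "3prime", "5prime")]
  right[, region := fifelse(strand == "-", "5prime", "3prime")]
  introns <- long[, if (.N > 1L) .(region = "intron", chrom = chrom[1L],
                                   start = ee[-.N], end = es[-1L],
                                   strand = strand[1L]),
                  by = transcript_id]
  introns <- if (nrow(introns)) introns[start < end] else
    data.table(transcript_id = character(), region = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character())
  out <- rbind(five_nc, coding, left, right,
               introns[, .(transcript_id, region, chrom, start, end, strand)])
  setorder(out, transcript_id, start)
  out[]
}

#' Keep high-confidence (RefSeq-supported) transcripts
#'
#' @param txs transcript table.
#' @param refseq_ids character set of supported transcript ids; a
#'   transcript is kept when flagged `refseq_supported` or listed here.
#' @return Filtered transcript table, input order preserved.
#' @export
filter_high_confidence <- function(txs, refseq_ids = character(0)) {
  txs[refseq_supported | transcript_id %in% refseq_ids]
}

#' Read a two-replicate FPKM expression table
#'
#' @param path TSV with header `transcript_id`, `fpkm_rep1`, `fpkm_rep2`.
#' @return `data.table` of the same columns.
#' @export
read_expression_table <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("transcript_id", "fpkm_rep1", "fpkm_rep2")
  if (!all(need %in% names(dt)))
    stop("expression table must have columns transcript_id, fpkm_rep1, fpkm_rep2")
  if (any(dt$fpkm_rep1 < 0) || any(dt$fpkm_rep2 < 0))
    stop("negative FPKM values")
  dt[, ..need]
}

#' Keep transcripts expressed in both replicates
#'
#' A transcript is retained iff an expression record exists and both
#' replicate FPKMs are strictly positive; the log10 of the replicate-mean
#' FPKM is attached as `log10_fpkm`.
#'
#' @param txs transcript table.
#' @param expr expression table ([read_expression_table()]).
#' @return Filtered transcript table with `log10_fpkm` attached.
#' @export
filter_expressed <- function(txs, expr) {
  keep <- expr[fpkm_rep1 > 0 & fpkm_rep2 > 0,
               .(transcript_id, log10_fpkm = log10((fpkm_rep1 + fpkm_rep2) / 2))]
  out <- merge(txs, keep, by = "transcript_id", sort = FALSE)
  out[]
}

#' Read a per-position CAGE TSS table
#'
#' @param path TSV with header `chrom`, `position` (0-based), `strand`,
#'   `tpm`.
#' @return `data.table` of those columns.
#' @export
read_ctss_table <- function(path) {
  dt <- fread(path, sep = "\t")
  need <- c("chrom", "position", "strand", "tpm")
  if (!all(need %in% names(dt)))
    stop("CTSS table must have columns chrom, position, strand, tpm")
  dt[, ..need]
}

#' Aggregate the most-correlated pair of CAGE replicates
#'
#' Picks the replicate pair with the highest Pearson correlation of
#' counts over shared positions, sums their counts and converts to tags
#' per million (TPM).
#'
#' @param replicates list of `data.table(chrom, position, strand, count)`.
#' @return `data.table(chrom, position, strand, tpm)`.
#' @export
aggregate_cage_replicates <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least two CAGE replicates")
  best <- c(NA_integer_, NA_integer_); best_rho <- -Inf
  for (i in seq_along(replicates)) for (j in seq_along(replicates)) {
    if (i >= j) next
    m <- merge(replicates[[i]], replicates[[j]],
               by = c("chrom", "position", "strand"))
    if (nrow(m) < 3L) next
    rho <- suppressWarnings(cor(m$count.x, m$count.y))
    if (!is.na(rho) && rho > best_rho) { best_rho <- rho; best <- c(i, j) }
  }
  if (is.na(best[1L])) stop("no replicate pair shares enough positions")
  m <- merge(replicates[[best[1L]]], replicates[[best[2L]]],
             by = c("chrom", "position", "strand"), all = TRUE)
  m[is.na(m)] <- 0
  m[, count := count.x + count.y]
  m[, tpm := count / sum(count) * 1e6]
  m[, .(chrom, position, strand, tpm)]
}

#' Cluster CAGE TSS positions into CTSS clusters
#'
#' Positions below the TPM threshold are excluded, then surviving
#' positions on the same chromosome and strand are merged into clusters
#' whenever consecutive gaps are at most `max_gap`. The dominant position
#' is the TPM argmax; ties go to the most 5' position in transcription
#' direction.
#'
#' @param ctss `data.table(chrom, position, strand, tpm)`, 0-based.
#' @param tpm_threshold minimum TPM for a position to enter clustering
#'   (`>=` retained).
#' @param max_gap maximum distance (bp) between consecutive member
#'   positions within one cluster.
#' @return `data.table` with one row per cluster: `chrom`, `strand`,
#'   `start_pos`, `end_pos` (member position range, inclusive), `width`,
#'   `dominant_pos`, `total_tpm`, `n_members`.
#' @export
cluster_ctss <- function(ctss, tpm_threshold = 0.1, max_gap = 20L) {
  if (nrow(ctss) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      start_pos = integer(), end_pos = integer(),
                      width = integer(), dominant_pos = integer(),
                      total_tpm = numeric(), n_members = integer()))
  if (any(ctss$tpm < 0)) stop("negative TPM values")
  dt <- as.data.table(ctss)[tpm >= tpm_threshold]
  if (nrow(dt) == 0L) return(cluster_ctss(ctss[0L], tpm_threshold, max_gap))
  setorder(dt, chrom, strand, position)
  dt[, gap := c(Inf, diff(position)), by = .(chrom, strand)]
  dt[, cluster_id := cumsum(gap > max_gap)]
  dt[, cluster_id := paste(chrom, strand, cluster_id, sep = ":")]
  dom <- function(position, tpm, strand) {
    cand <- position[tpm == max(tpm)]
    if (strand[1L] == "-") max(cand) else min(cand)
  }
  out <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                start_pos = min(position), end_pos = max(position),
                width = max(position) - min(position) + 1L,
                dominant_pos = dom(position, tpm, strand),
                total_tpm = sum(tpm), n_members = .N),
            by = cluster_id][, cluster_id := NULL]
  out[]
}

#' Keep transcripts whose TSS is a dominant CTSS
#'
#' @param txs transcript table.
#' @param clusters output of [cluster_ctss()].
#' @param tolerance maximum |TSS - dominant position| in bp (same strand);
#'   default 0, i.e. exact match.
#' @return Filtered transcript table with `tss_cluster_width`,
#'   `tss_cluster_start`, `tss_cluster_end` attached from the matching
#'   cluster.
#' @export
filter_by_dominant_ctss <- function(txs, clusters, tolerance = 0L) {
  if (nrow(txs) == 0L || nrow(clusters) == 0L) return(txs[0L])
  tssv <- tss_position(txs)
  keep <- logical(nrow(txs))
  width <- integer(nrow(txs)); cs <- integer(nrow(txs)); ce <- integer(nrow(txs))
  cl <- as.data.table(clusters)
  for (i in seq_len(nrow(txs))) {
    cand <- cl[chrom == txs$chrom[i] & strand == txs$strand[i] &
                 abs(dominant_pos - tssv[i]) <= tolerance]
    if (nrow(cand)) {
      cand <- cand[which.min(abs(dominant_pos - tssv[i]))]
      keep[i] <- TRUE
      width[i] <- cand$width; cs[i] <- cand$start_pos; ce[i] <- cand$end_pos
    }
  }
  out <- txs[keep]
  out[, `:=`(tss_cluster_width = width[keep],
             tss_cluster_start = cs[keep],
             tss_cluster_end = ce[keep])]
  out[]
}
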