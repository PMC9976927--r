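# Readers/writers for the standard formats the pipeline touches. All
# readers normalize to the internal 0-based half-open convention; all
# writers convert back to each format's native convention.

#' Read transcript models from a GTF file
#'
#' Parses GENCODE-dialect GTF (1-based inclusive coordinates) into a
#' transcript table with 0-based half-open coordinates and exons ordered
#' 5' to 3' in transcription direction. CDS records, when present, are
#' collapsed to a genomic CDS span per transcript.
#'
#' @param path GTF file path.
#' @param attributes_required attribute tags that must be present on every
#'   transcript and exon record; a missing tag is a parse error naming the
#'   offending record.
#' @return A `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `gene_symbol`, `chrom`, `strand`, `start`, `end`,
#'   `biotype`, `refseq_supported`, `cds_start`, `cds_end` (NA when the
#'   transcript has no CDS) and a list-column `exons` of
#'   `data.table(start, end)` in transcription order.
#' @export
read_gtf_transcripts <- function(path,
                                 attributes_required = c("gene_id",
                                                         "transcript_id")) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("transcript", "exon", "CDS")
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]; type <- type[keep]
  rec_no <- which(keep) # record index in file order, for error messages

  for (tag in attributes_required) {
    vals <- if (tag %in% colnames(md)) md[[tag]] else rep(NA_character_, length(gr))
    bad <- which(is.na(vals) & type %in% c("transcript", "exon"))
    if (length(bad))
      stop(sprintf("GTF record %d lacks required attribute '%s'",
                   rec_no[bad[1L]], tag))
  }

  get_attr <- function(name, default = NA_character_) {
    if (name %in% colnames(md)) as.character(md[[name]])
    else rep(default, length(gr))
  }
  dt <- data.table(
    type = type,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = get_attr("gene_id"),
    transcript_id = get_attr("transcript_id"),
    gene_symbol = get_attr("gene_name", ""),
    biotype = {
      b <- get_attr("transcript_type")
      if (all(is.na(b))) b <- get_attr("transcript_biotype")
      if (all(is.na(b))) b <- get_attr("gene_biotype", "")
      b
    },
    refseq_supported = tolower(get_attr("refseq_supported", "false")) %in%
      c("true", "1", "yes")
  )

  txr <- dt[type == "transcript"]
  if (nrow(txr) == 0L) stop("GTF contains no transcript records")
  exr <- dt[type == "exon"]
  cdr <- dt[type == "CDS"]

  exons_by_tx <- split(exr[, .(start, end)], exr$transcript_id)
  cds_by_tx <- if (nrow(cdr)) {
    cdr[, .(cds_start = min(start), cds_end = max(end)), by = transcript_id]
  } else data.table(transcript_id = character(), cds_start = integer(),
                    cds_end = integer())

  out <- txr[, .(transcript_id, gene_id, gene_symbol, chrom, strand,
                 start, end, biotype, refseq_supported)]
  out <- merge(out, cds_by_tx, by = "transcript_id", all.x = TRUE,
               sort = FALSE)
  out[, exons := lapply(transcript_id, function(id) {
    ex <- exons_by_tx[[id]]
    if (is.null(ex)) stop(sprintf("transcript '%s' has no exon records", id))
    ex <- ex[order(start)]
    data.table(start = ex$start, end = ex$end)
  })]
  # validate exons within span, then order in transcription direction
  for (i in seq_len(nrow(out))) {
    ex <- out$exons[[i]]
    if (any(ex$start < out$start[i]) || any(ex$end > out$end[i]))
      stop(sprintf("exon outside transcript span for '%s'",
                   out$transcript_id[i]))
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop(sprintf("overlapping exons in transcript '%s'",
                   out$transcript_id[i]))
    if (out$strand[i] == "-") out$exons[[i]] <- ex[rev(seq_len(nrow(ex)))]
  }
  out[]
}

#' Write transcript models to GTF
#'
#' Inverse of [read_gtf_transcripts()]: emits transcript, exon and CDS
#' records with 1-based inclusive coordinates.
#'
#' @param txs transcript table as returned by [read_gtf_transcripts()].
#' @param path output file path.
#' @export
write_gtf_transcripts <- function(txs, path) {
  fmt_attr <- function(gene_id, tx_id, symbol, biotype, refseq) {
    sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_name "%s"; ',
                   'transcript_type "%s"; refseq_supported "%s";'),
            gene_id, tx_id, symbol, biotype,
            ifelse(refseq, "true", "false"))
  }
  lines <- character(0)
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i]
    attr <- fmt_attr(tx$gene_id, tx$transcript_id, tx$gene_symbol,
                     tx$biotype, tx$refseq_supported)
    row <- function(type, s0, e0) {
      sprintf("%s\tpausescape\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom, type, s0 + 1L, e0, tx$strand, attr)
    }
    lines <- c(lines, row("transcript", tx$start, tx$end))
    ex <- tx$exons[[1L]]
    for (j in seq_len(nrow(ex))) lines <- c(lines, row("exon", ex$start[j], ex$end[j]))
    if (!is.na(tx$cds_start))
      lines <- c(lines, row("CDS", tx$cds_start, tx$cds_end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks from a BED file
#'
#' BED3+ (0-based half-open) intervals are preserved bit-exact and tagged
#' with the originating factor and assay. The strand column (field 6) is
#' used for `clip` peaks when present and ignored for `chip` peaks, which
#' are treated as strandless.
#'
#' @param path BED file path.
#' @param factor factor (protein) name tag.
#' @param assay `"chip"` (DNA binding, strandless) or `"clip"` (RNA
#'   binding, strand-aware).
#' @return `data.table(chrom, start, end, strand, factor_name, assay)`.
#' @export
read_bed_peaks <- function(path, factor, assay = c("chip", "clip")) {
  assay <- match.arg(assay)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      factor_name = character(), assay = character())
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3L)[1L], path))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 bad[1L], path))
  strand <- rep(".", length(lines))
  if (assay == "clip") {
    has6 <- nf >= 6L
    strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
    strand[!strand %in% c("+", "-")] <- "."
  }
  out <- data.table(chrom = chrom, start = start, end = end,
                    strand = strand, factor_name = factor, assay = assay)
  validate_intervals(out)
  out
}

#' Write peaks to a BED6 file
#'
#' @param peaks interval table (`chrom`, `start`, `end`, `strand`).
#' @param path output file path.
#' @export
write_bed_peaks <- function(peaks, path) {
  if (nrow(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dt <- data.table(peaks$chrom, peaks$start, peaks$end, ".", 0L,
                   peaks$strand)
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a strand-resolved coverage track
#'
#' @param positions `data.table(chrom, strand, pos, value)` with `pos`
#'   0-based and `value >= 0`; duplicate (chrom, strand, pos) rows are an
#'   error when their values conflict.
#' @param genome_tag optional genome build label.
#' @return A keyed `data.table` of class `signal_track`.
#' @export
signal_track <- function(positions, genome_tag = NA_character_) {
  dt <- as.data.table(positions)[, .(chrom = as.character(chrom),
                                     strand = as.character(strand),
                                     pos = as.integer(pos),
                                     value = as.numeric(value))]
  if (any(dt$value < 0)) stop("signal track values must be non-negative")
  if (any(!dt$strand %in% c("+", "-")))
    stop("signal track strand must be '+' or '-'")
  dup <- dt[, .N, by = .(chrom, strand, pos)][N > 1L]
  if (nrow(dup)) {
    conf <- dt[dup, on = .(chrom, strand, pos)][
      , .(nval = uniqueN(value)), by = .(chrom, strand, pos)]
    if (any(conf$nval > 1L))
      stop("conflicting coverage declarations for the same position/strand")
    dt <- unique(dt)
  }
  dt <- dt[value > 0]
  setkey(dt, chrom, strand, pos)
  setattr(dt, "genome_tag", genome_tag)
  setattr(dt, "class", c("signal_track", class(dt)))
  dt[]
}

#' Read strand-specific coverage from wiggle files
#'
#' Supports the two strand dialects found in GEO GRO-seq deposits: a
#' plus/minus file pair (both files hold non-negative values) or a single
#' signed file in which negative values denote minus-strand coverage and
#' are stored as magnitudes. Wiggle positions are 1-based and shifted to
#' the internal 0-based convention.
#'
#' @param plus_path wig file for the plus strand (or the single signed
#'   file when `convention = "signed"`).
#' @param minus_path wig file for the minus strand (two-file mode only).
#' @param convention `"two_files"` (default) or `"signed"`.
#' @param genome_tag optional genome build label.
#' @return A [signal_track()].
#' @export
read_wig_signal <- function(plus_path, minus_path = NULL,
                            convention = c("two_files", "signed"),
                            genome_tag = NA_character_) {
  convention <- match.arg(convention)
  import_one <- function(path) {
    gr <- rtracklayer::import(path, format = "wig")
    w <- GenomicRanges::width(gr)
    st <- GenomicRanges::start(gr)
    data.table(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
      # expand spans to per-base positions, shifted to 0-based
      pos = rep(st, w) + sequence(w) - 2L,
      value = rep(as.numeric(gr$score), w))
  }
  if (convention == "two_files") {
    if (is.null(minus_path))
      stop("two-file convention requires a minus-strand wig file")
    p <- import_one(plus_path); p[, strand := "+"]
    m <- import_one(minus_path); m[, strand := "-"]
    if (any(p$value < 0) || any(m$value < 0))
      stop("two-file wig pair must hold non-negative values")
    dt <- rbind(p, m)
  } else {
    dt <- import_one(plus_path)
    dt[, strand := ifelse(value < 0, "-", "+")]
    dt[, value := abs(value)]
  }
  signal_track(dt[, .(chrom, strand, pos, value)], genome_tag = genome_tag)
}

#' Write a coverage track as a plus/minus wiggle file pair
#'
#' Positions are emitted 1-based in variableStep blocks, magnitudes on
#' both strands (the two-file dialect read back by [read_wig_signal()]).
#'
#' @param track a [signal_track()].
#' @param plus_path,minus_path output file paths.
#' @export
write_wig_signal <- function(track, plus_path, minus_path) {
  write_one <- function(dt, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (ch in unique(dt$chrom)) {
      writeLines(sprintf("variableStep chrom=%s", ch), con)
      sub <- dt[chrom == ch][order(pos)]
      writeLines(paste(sub$pos + 1L, format(sub$value, scientific = FALSE,
                                            trim = TRUE)), con)
    }
    invisible(path)
  }
  write_one(track[strand == "+"], plus_path)
  write_one(track[strand == "-"], minus_path)
  invisible(c(plus_path, minus_path))
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path; duplicate record names are an error.
#' @return An upper-cased `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in FASTA")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a genome to FASTA
#' @param genome a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Extract genome sequence for an interval
#'
#' @param genome `DNAStringSet` from [read_fasta()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates; out-of-bounds lookups
#'   are errors.
#' @return Character scalar sequence (plus-strand orientation).
#' @export
get_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' not in genome", chrom))
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

# Vectorized letter-fraction over intervals (0-based half-open), using
# per-chromosome views; `letters` as in Biostrings::letterFrequency.
seq_letter_fraction <- function(genome, chrom, start, end, letters) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = start[i] + 1L, end = end[i])
    f <- Biostrings::letterFrequency(v, letters = letters)
    out[i] <- rowSums(f) / (end[i] - start[i])
  }
  out
}

# Vectorized test for any base outside {A, C, G, T} in each interval.
seq_has_non_acgt <- function(genome, chrom, start, end) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = start[i] + 1L, end = end[i])
    f <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    out[i] <- f[, "other"] > 0L
  }
  out
}
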