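# Internal coordinate convention: 0-based, half-open [start, end),
# strand one of "+", "-", ".".  GTF (1-based inclusive) and wiggle
# (1-based) inputs are converted on read; writers convert back.

#' Create a genomic interval table
#'
#' Intervals are the package-wide currency for peaks and regions. They use
#' 0-based half-open coordinates and carry a strand in `{+, -, .}`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand character vector in `{+, -, .}` (recycled).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  iv <- data.table(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)))
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom)))
    stop("interval with empty chromosome name")
  if (any(iv$start < 0L)) stop("interval with negative start")
  if (any(iv$start >= iv$end)) stop("interval with start >= end")
  if (any(!iv$strand %in% c("+", "-", ".")))
    stop("interval strand must be one of '+', '-', '.'")
  invisible(iv)
}

# Set intersection of one interval set with a single window [s, e).
# Both 0-based half-open; returns possibly empty data.table(start, end).
clip_intervals <- function(iv, s, e) {
  if (nrow(iv) == 0L || s >= e) return(iv[0L, .(start, end)])
  out <- iv[, .(start = pmax(start, as.integer(s)),
                end = pmin(end, as.integer(e)))]
  out[start < end]
}

# Complement of sorted non-overlapping intervals within a span [s, e).
gaps_in_span <- function(iv, s, e) {
  if (nrow(iv) == 0L)
    return(data.table(start = as.integer(s), end = as.integer(e)))
  iv <- iv[order(start)]
  bounds <- c(s, as.vector(rbind(iv$start, iv$end)), e)
  starts <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
  ends <- bounds[seq(2L, length(bounds), by = 2L)]
  out <- data.table(start = as.integer(starts), end = as.integer(ends))
  out[start < end]
}

interval_width <- function(iv) {
  if (nrow(iv) == 0L) return(0L)
  sum(iv$end - iv$start)
}

# TSS (0-based position of the first transcribed base) for transcript rows.
tss_position <- function(tx) {
  ifelse(tx$strand == "+", tx$start, tx$end - 1L)
}
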