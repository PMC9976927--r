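# Pausing-index quantification: windowed coverage sums, the log2 PI,
# TSS window-size optimization and the transcript exclusion filters.

#' Pausing-index configuration
#'
#' @param tss_halfwidth TSS window half-width `h` (window spans
#'   `[TSS - h, TSS + h]`, i.e. `2h + 1` bp).
#' @param pseudocount pseudocount (reads) added to each window count
#'   before length normalization.
#' @param halfwidth_grid candidate half-widths for
#'   [optimize_tss_window()].
#' @return A list of class `pi_config`.
#' @export
pi_config <- function(tss_halfwidth = 1L, pseudocount = 1,
                      halfwidth_grid = c(1L, 2L, 5L, 10L, 25L, 50L, 100L,
                                         250L, 500L, 1000L)) {
  stopifnot(tss_halfwidth >= 0L, pseudocount > 0)
  structure(list(tss_halfwidth = as.integer(tss_halfwidth),
                 pseudocount = pseudocount,
                 halfwidth_grid = as.integer(halfwidth_grid)),
            class = "pi_config")
}

#' Sum coverage over an interval
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @param strand `"+"` or `"-"`.
#' @return Total coverage in `[start, end)` on the given strand.
#' @export
window_signal <- function(track, chrom, start, end, strand) {
  stopifnot(strand %in% c("+", "-"))
  ch <- chrom; st <- strand # avoid column-name capture in the join
  sub <- track[.(ch, st), nomatch = NULL]
  if (nrow(sub) == 0L) return(0)
  sum(sub$value[sub$pos >= start & sub$pos < end])
}

# TSS and body window coordinates for a transcript (internal 0-based
# half-open). TSS window is centered and inclusive: [TSS-h, TSS+h]; the
# body is the remainder of the unspliced span downstream in transcription
# direction. The normalization length w_body is span length - w_tss, so
# that the two window lengths partition the transcript length.
pi_windows <- function(tx_start, tx_end, strand, h) {
  tss <- if (strand == "+") tx_start else tx_end - 1L
  tss_s <- tss - h; tss_e <- tss + h + 1L
  if (strand == "+") {
    body_s <- tss + h + 1L; body_e <- tx_end
  } else {
    body_s <- tx_start; body_e <- tss - h
  }
  list(tss_start = tss_s, tss_end = tss_e,
       body_start = body_s, body_end = body_e)
}

#' Compute the pausing index for one transcript
#'
#' The pausing index is the log2 ratio of length-normalized coverage in a
#' sharp TSS window versus the gene body:
#' `pi = log2((c_tss + a) / w_tss) - log2((c_body + a) / w_body)` with
#' pseudocount `a` added to the raw window read counts. The TSS window is
#' `[TSS - h, TSS + h]`; the body is the remaining unspliced span
#' downstream in transcription direction, normalized by
#' `w_body = span length - w_tss`.
#'
#' @param track a [signal_track()].
#' @param tx a single transcript row.
#' @param cfg a [pi_config()].
#' @return `data.table(transcript_id, c_tss, c_body, w_tss, w_body, pi)`.
#' @export
compute_pausing_index <- function(track, tx, cfg = pi_config()) {
  h <- cfg$tss_halfwidth
  w_tss <- 2L * h + 1L
  len <- tx$end - tx$start
  if (len <= w_tss)
    stop(sprintf("transcript '%s' shorter than the TSS window",
                 tx$transcript_id))
  w <- pi_windows(tx$start, tx$end, tx$strand, h)
  c_tss <- window_signal(track, tx$chrom, w$tss_start, w$tss_end, tx$strand)
  c_body <- window_signal(track, tx$chrom, w$body_start, w$body_end, tx$strand)
  w_body <- len - w_tss
  a <- cfg$pseudocount
  data.table(transcript_id = tx$transcript_id, c_tss = c_tss,
             c_body = c_body, w_tss = w_tss, w_body = w_body,
             pi = log2((c_tss + a) / w_tss) - log2((c_body + a) / w_body))
}

#' Pausing indices for a transcript table
#'
#' Vectorized version of [compute_pausing_index()].
#'
#' @inheritParams compute_pausing_index
#' @param txs transcript table; transcripts not longer than the TSS
#'   window are an error.
#' @return One [compute_pausing_index()] row per transcript.
#' @export
compute_pausing_table <- function(track, txs, cfg = pi_config()) {
  h <- cfg$tss_halfwidth
  w_tss <- 2L * h + 1L
  len <- txs$end - txs$start
  if (any(len <= w_tss))
    stop("transcripts not longer than the TSS window present")
  tss <- tss_position(txs)
  win <- data.table(
    transcript_id = rep(txs$transcript_id, 2L),
    chrom = rep(txs$chrom, 2L),
    strand = rep(txs$strand, 2L),
    ws = c(tss - h, ifelse(txs$strand == "+", tss + h + 1L, txs$start)),
    we = c(tss + h + 1L, ifelse(txs$strand == "+", txs$end, tss - h)),
    which = rep(c("tss", "body"), each = nrow(txs)))
  win[we < ws, we := ws] # degenerate body on tiny spans: zero-width
  sums <- track[win, on = .(chrom, strand, pos >= ws, pos < we),
                .(total = sum(value)), by = .EACHI]
  win[, total := fifelse(is.na(sums$total), 0, sums$total)]
  wide <- dcast(win, transcript_id ~ which, value.var = "total")
  wide <- wide[match(txs$transcript_id, transcript_id)]
  a <- cfg$pseudocount
  out <- data.table(transcript_id = txs$transcript_id,
                    c_tss = wide$tss, c_body = wide$body,
                    w_tss = w_tss, w_body = len - w_tss)
  out[, pi := log2((c_tss + a) / w_tss) - log2((c_body + a) / w_body)]
  out[]
}

#' Optimize the TSS window half-width
#'
#' Scans a grid of half-widths; for each, computes all pausing indices
#' and their Pearson correlation with log10 FPKM, and returns the
#' half-width with the most negative correlation (high pausing should
#' mean low expression). Ties go to the smallest half-width.
#'
#' @param track a [signal_track()].
#' @param txs transcript table with `log10_fpkm` attached
#'   ([filter_expressed()]).
#' @param grid integer half-width candidates.
#' @param pseudocount pseudocount passed through to the PI.
#' @return A list with `best_halfwidth` and `profile`
#'   (`data.table(halfwidth, rho, n)`).
#' @export
optimize_tss_window <- function(track, txs,
                                grid = c(1L, 2L, 5L, 10L, 25L, 50L, 100L,
                                         250L, 500L, 1000L),
                                pseudocount = 1) {
  if (!"log10_fpkm" %in% names(txs))
    stop("txs must carry log10_fpkm (run filter_expressed first)")
  if (var(txs$log10_fpkm) == 0)
    stop("zero expression variance: correlation undefined")
  grid <- sort(unique(as.integer(grid)))
  prof <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    h <- grid[k]
    ok <- txs[(end - start) > 2L * h + 1L]
    if (nrow(ok) < 3L)
      stop(sprintf("fewer than 3 usable transcripts at halfwidth %d", h))
    pit <- compute_pausing_table(track, ok, pi_config(h, pseudocount))
    rho <- cor(pit$pi, ok$log10_fpkm)
    prof[[k]] <- data.table(halfwidth = h, rho = rho, n = nrow(ok))
  }
  profile <- rbindlist(prof)
  # ties (to numerical precision): smallest halfwidth wins
  near_min <- profile$rho <= min(profile$rho) + 1e-12
  best <- min(profile$halfwidth[near_min])
  list(best_halfwidth = best, profile = profile)
}

#' Apply the pausing-index transcript exclusion filters
#'
#' Excludes (i) transcripts whose span sequence contains a letter outside
#' `{A, C, G, T}`, (ii) every member of a same-strand span-overlapping
#' pair of transcripts (coverage cannot be uniquely ascribed), and (iii)
#' transcripts with zero coverage in both the TSS window and the body.
#'
#' @param txs transcript table (protein-coding, expressed).
#' @param genome `DNAStringSet` covering all transcripts.
#' @param track a [signal_track()].
#' @param cfg a [pi_config()] (fixes the windows for the zero-signal
#'   rule).
#' @param same_strand_only when `TRUE` (default) the overlap rule only
#'   considers same-strand pairs; nascent coverage is strand-separable.
#' @return A list with `retained` (filtered transcript table) and
#'   `report` (`data.table(reason, n)` with reasons `non_acgt`,
#'   `overlap`, `no_signal`, `retained`).
#' @export
apply_pi_filters <- function(txs, genome, track, cfg = pi_config(),
                             same_strand_only = TRUE) {
  n0 <- nrow(txs)
  non_acgt <- seq_has_non_acgt(genome, txs$chrom, txs$start, txs$end)

  overlap <- logical(n0)
  dt <- data.table(idx = seq_len(n0), chrom = txs$chrom,
                   start = txs$start, end = txs$end, strand = txs$strand)
  grp <- if (same_strand_only) c("chrom", "strand") else "chrom"
  for (g in split(dt, by = grp)) {
    if (nrow(g) < 2L) next
    setorder(g, start)
    # sweep: a transcript overlaps its predecessor set iff its start is
    # before the running max end
    run_end <- cummax(g$end)
    hit <- g$start[-1L] < run_end[-nrow(g)]
    if (any(hit)) {
      for (i in which(hit)) {
        overlap[g$idx[i + 1L]] <- TRUE
        partners <- which(g$end[seq_len(i)] > g$start[i + 1L])
        overlap[g$idx[partners]] <- TRUE
      }
    }
  }

  pit <- compute_pausing_table(track, txs, cfg)
  no_signal <- pit$c_tss == 0 & pit$c_body == 0

  drop <- non_acgt | overlap | no_signal
  report <- data.table(
    reason = c("non_acgt", "overlap", "no_signal", "retained"),
    n = c(sum(non_acgt), sum(overlap), sum(no_signal), sum(!drop)))
  list(retained = txs[!drop], report = report)
}
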