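# Independent brute-force reference implementations. These deliberately
# use naive per-base / per-pair loops so that the package's vectorized
# code is checked against a different computational route.

# total coverage by scanning every track row
oracle_window_signal <- function(track, chrom, start, end, strand) {
  tot <- 0
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] == chrom && track$strand[i] == strand &&
        track$pos[i] >= start && track$pos[i] < end)
      tot <- tot + track$value[i]
  }
  tot
}

# pausing index from raw counts by direct arithmetic
oracle_pi <- function(c_tss, c_body, w_tss, w_body, a = 1) {
  log2((c_tss + a) / w_tss) - log2((c_body + a) / w_body)
}

# per-base region classification for one transcript
oracle_region_labels <- function(tx) {
  pos <- tx$start:(tx$end - 1L)
  ex <- tx$exons[[1L]]
  exonic <- rep(FALSE, length(pos))
  for (j in seq_len(nrow(ex)))
    exonic[pos >= ex$start[j] & pos < ex$end[j]] <- TRUE
  lab <- rep("intron", length(pos))
  if (is.na(tx$cds_start)) {
    lab[exonic] <- "5prime"
  } else {
    left <- pos < tx$cds_start
    right <- pos >= tx$cds_end
    mid <- !left & !right
    lab[exonic & mid] <- "codingexon"
    lab[exonic & left] <- if (tx$strand == "+") "5prime" else "3prime"
    lab[exonic & right] <- if (tx$strand == "+") "3prime" else "5prime"
  }
  setNames(lab, pos)
}

# expand a region set (list of interval tables) to per-base labels
expand_regions <- function(rs, tx) {
  pos <- tx$start:(tx$end - 1L)
  lab <- rep(NA_character_, length(pos))
  names(lab) <- pos
  token <- c(five_prime = "5prime", coding_exons = "codingexon",
             introns = "intron", three_prime = "3prime")
  for (nm in names(rs)) {
    iv <- rs[[nm]]
    for (j in seq_len(nrow(iv)))
      lab[as.character(iv$start[j]:(iv$end[j] - 1L))] <- token[[nm]]
  }
  lab
}

# O(n*m) interval-overlap scan for binding flags
oracle_binding_flag <- function(region_ivs, peaks, stranded) {
  for (i in seq_len(nrow(region_ivs))) {
    for (j in seq_len(nrow(peaks))) {
      if (region_ivs$chrom[i] != peaks$chrom[j]) next
      if (stranded && peaks$strand[j] %in% c("+", "-") &&
          peaks$strand[j] != region_ivs$strand[i]) next
      if (peaks$start[j] < region_ivs$end[i] &&
          region_ivs$start[i] < peaks$end[j]) return(1L)
    }
  }
  0L
}

# naive CTSS clustering by linear scan
oracle_cluster_ctss <- function(ctss, thr, max_gap) {
  dt <- ctss[ctss$tpm >= thr, ]
  if (nrow(dt) == 0L) return(NULL)
  dt <- dt[order(dt$chrom, dt$strand, dt$position), ]
  out <- list()
  cur <- dt[1, , drop = FALSE]
  flush <- function(cur) {
    best <- which(cur$tpm == max(cur$tpm))
    dom <- if (cur$strand[1] == "-") max(cur$position[best]) else
      min(cur$position[best])
    data.frame(chrom = cur$chrom[1], strand = cur$strand[1],
               start_pos = min(cur$position), end_pos = max(cur$position),
               width = diff(range(cur$position)) + 1L, dominant_pos = dom,
               total_tpm = sum(cur$tpm), n_members = nrow(cur))
  }
  for (i in seq_len(nrow(dt))[-1]) {
    same <- dt$chrom[i] == cur$chrom[1] && dt$strand[i] == cur$strand[1]
    if (same && dt$position[i] - max(cur$position) <= max_gap) {
      cur <- rbind(cur, dt[i, ])
    } else {
      out[[length(out) + 1L]] <- flush(cur)
      cur <- dt[i, , drop = FALSE]
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  do.call(rbind, out)
}

# one-sided (greater) Fisher p by explicit hypergeometric enumeration
oracle_fisher_greater <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}
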