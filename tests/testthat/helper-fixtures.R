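library(data.table)

# Shared fixture cache: small synthetic bundles and pipeline runs are
# expensive enough to build once per test session.
.fixture_env <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_genes = 250L, n_ncrnas = 20L,
                                 n_factors = 20L, n_causal = 5L),
                            list(...))
  do.call(generator_config, args)
}

fast_spec <- function(seed = 1L, ...) {
  model_spec(eta = 0.1, max_depth = 4L, nrounds_max = 300L,
             early_stopping = 25L, n_folds = 3L, seed = seed, ...)
}

cached_bundle <- function(key = "default", cfg = small_cfg(), seed = 1L) {
  k <- paste0("bundle_", key)
  if (is.null(.fixture_env[[k]])) {
    dir <- file.path(tempdir(), paste0("pausescape_bundle_", key))
    .fixture_env[[k]] <- simulate_bundle(cfg, dir, seed = seed)
  }
  .fixture_env[[k]]
}

cached_run <- function() {
  if (is.null(.fixture_env$run)) {
    b <- cached_bundle()
    .fixture_env$run <- run_pipeline(dirname(b$paths$genome),
                                     spec = fast_spec())
  }
  .fixture_env$run
}

make_tx <- function(id = "tx1", chrom = "chr1", strand = "+", start = 0L,
                    end = 100L, exons = NULL, cds = c(NA, NA),
                    biotype = "protein_coding", refseq = TRUE) {
  if (is.null(exons))
    exons <- data.table(start = as.integer(start), end = as.integer(end))
  ex <- as.data.table(exons)
  if (strand == "-") ex <- ex[rev(order(start))]
  data.table(transcript_id = id, gene_id = paste0("g_", id),
             gene_symbol = toupper(id), chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end),
             biotype = biotype, refseq_supported = refseq,
             cds_start = as.integer(cds[1L]), cds_end = as.integer(cds[2L]),
             exons = list(ex))
}

make_track <- function(chrom, strand, pos, value) {
  signal_track(data.table(chrom = chrom, strand = strand,
                          pos = as.integer(pos), value = value))
}

make_genome <- function(...) Biostrings::DNAStringSet(c(...))

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
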