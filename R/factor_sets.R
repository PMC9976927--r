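# Functional factor sets (GO-derived plus literature extension), 7SK
# binder identification, sequence-specificity stratification, feature
# subsetting and randomized baseline matrices.

#' Construct a factor set
#'
#' @param name set name (e.g. `"Elongation"`, `"7SK.Binding"`).
#' @param members character vector of factor names (unique).
#' @param provenance optional per-member source tag, recycled.
#' @return A list of class `factor_set` with `name`, `members`,
#'   `provenance`.
#' @export
factor_set <- function(name, members, provenance = NA_character_) {
  members <- as.character(members)
  if (anyDuplicated(members)) stop("duplicate members in factor set")
  structure(list(name = name, members = members,
                 provenance = rep_len(provenance, length(members))),
            class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("factor_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

extdata <- function(file) {
  system.file("extdata", file, package = "pausescape", mustWork = TRUE)
}

#' Default GO biological-process term map for functional sets
#'
#' Maps each functional set name to the GO ids whose annotation defines
#' membership: Chromatin (chromosome organization GO:0051276, chromatin
#' organization GO:0006325, chromatin remodeling GO:0006338), Initiation
#' (PIC assembly GO:0051123, Pol II transcription initiation GO:0006367),
#' Elongation (Pol II transcription elongation GO:0006368), Termination
#' (GO:0006369), Splicing (spliceosomal mRNA splicing GO:0045292,
#' regulation of alternative splicing GO:0000381) and Processing (mRNA
#' export GO:0006406, mRNA 3'-end processing GO:0031124).
#'
#' @return Named list of GO id character vectors.
#' @export
default_go_term_map <- function() {
  list(Chromatin = c("GO:0051276", "GO:0006325", "GO:0006338"),
       Initiation = c("GO:0051123", "GO:0006367"),
       Elongation = "GO:0006368",
       Termination = "GO:0006369",
       Splicing = c("GO:0045292", "GO:0000381"),
       Processing = c("GO:0006406", "GO:0031124"))
}

#' Literature pause-regulatory factors
#'
#' The packaged list of established pause-regulatory factors used to
#' extend the GO-derived Elongation set: super elongation complex
#' members, core pausing factors (NELF/DSIF subunits, BRD4, MYC, TAF1,
#' TBP, PAF1, CDK9) and 7SK snRNP components (LARP7, HEXIM1/2, MEPCE).
#'
#' @return `data.table(factor, group)`.
#' @export
literature_pausing_factors <- function() {
  fread(extdata("elongation_literature_factors.tsv"), sep = "\t")
}

#' Reference Elongation factor set (K562)
#'
#' The 19 established pausing factors assayed in the K562 ChIP/eCLIP
#' experiments (GO-derived members plus the literature extension),
#' including the four Pol II subunits. Pol II (POLR2*) columns never
#' enter default feature matrices, so they are harmless here and are
#' retained for bookkeeping.
#'
#' @return A [factor_set()] named `"Elongation"`.
#' @export
reference_elongation_set <- function() {
  dt <- fread(extdata("k562_elongation_set.tsv"), sep = "\t")
  factor_set("Elongation", dt$factor, dt$provenance)
}

#' Reference 7SK-binding factor set (K562)
#'
#' Factors with at least one eCLIP binding site on a 7SK transcript:
#' the established 7SK snRNP component LARP7 plus 16 factors not
#' previously associated with 7SK (AQR and 15 further factors).
#'
#' @return `data.table(factor, status)` with `status` in
#'   `{known, novel}`.
#' @export
reference_7sk_binders <- function() {
  fread(extdata("k562_7sk_binders.tsv"), sep = "\t")
}

#' Build functional factor sets from GO annotations
#'
#' A factor belongs to a set iff it is annotated to any of the set's
#' mapped GO terms. The Elongation set is additionally unioned with the
#' literature extension (restricted to assayed factors when an assayed
#' universe is given).
#'
#' @param go_annotations `data.table(factor, go_id)` membership table
#'   (memberships are taken as given; no ontology propagation).
#' @param term_map named list set name -> GO id vector
#'   ([default_go_term_map()]).
#' @param literature_extension character vector of factors unioned into
#'   Elongation (default: packaged list).
#' @param assayed_factors optional universe; when given, all sets are
#'   restricted to it.
#' @return Named list of [factor_set()]s.
#' @export
build_functional_sets <- function(go_annotations,
                                  term_map = default_go_term_map(),
                                  literature_extension =
                                    literature_pausing_factors()$factor,
                                  assayed_factors = NULL) {
  go <- as.data.table(go_annotations)
  if (!all(c("factor", "go_id") %in% names(go)))
    stop("go_annotations must have columns factor, go_id")
  if (any(!grepl("^GO:\\d{7}$", unlist(term_map))))
    stop("malformed GO id in term map")
  sets <- list()
  for (nm in names(term_map)) {
    members <- unique(go[go_id %in% term_map[[nm]]]$factor)
    prov <- rep("go", length(members))
    if (nm == "Elongation") {
      extra <- setdiff(literature_extension, members)
      if (!is.null(assayed_factors))
        extra <- intersect(extra, assayed_factors)
      members <- c(members, extra)
      prov <- c(prov, rep("literature", length(extra)))
    }
    if (!is.null(assayed_factors)) {
      keep <- members %in% assayed_factors
      members <- members[keep]; prov <- prov[keep]
    }
    sets[[nm]] <- factor_set(nm, members, prov)
  }
  sets
}

#' Identify 7SK-binding factors from CLIP peaks
#'
#' The 7SK transcript target set is all non-pseudo 7SK transcripts plus
#' pseudo copies expressed at least at the median expression of all
#' expressed non-coding transcripts. A factor is a 7SK binder iff at
#' least one of its CLIP peaks overlaps any target transcript on the
#' same strand.
#'
#' @param ncrna_txs non-coding transcript table with `gene_symbol`.
#' @param clip_peaks CLIP peak table ([read_bed_peaks()]).
#' @param ncrna_expression `data.table(transcript_id, fpkm_rep1,
#'   fpkm_rep2)` for expressed ncRNA transcripts.
#' @param gene_pattern regex selecting 7SK genes (default `^RN7SK`);
#'   pseudo copies are recognized by `pseudo_pattern`.
#' @param pseudo_pattern regex selecting pseudo 7SK copies.
#' @return A [factor_set()] named `"7SK.Binding"`; empty (with a
#'   warning) when no 7SK transcript is found.
#' @export
identify_7sk_binders <- function(ncrna_txs, clip_peaks, ncrna_expression,
                                 gene_pattern = "^RN7SK",
                                 pseudo_pattern = "^RN7SKP") {
  sevenk <- ncrna_txs[grepl(gene_pattern, gene_symbol)]
  if (nrow(sevenk) == 0L) {
    warning("no 7SK transcript found")
    return(factor_set("7SK.Binding", character(0)))
  }
  expr <- as.data.table(ncrna_expression)
  expr <- expr[fpkm_rep1 > 0 & fpkm_rep2 > 0]
  expr[, fpkm := (fpkm_rep1 + fpkm_rep2) / 2]
  med <- median(expr$fpkm)
  is_pseudo <- grepl(pseudo_pattern, sevenk$gene_symbol)
  pseudo_expr <- expr[match(sevenk$transcript_id, transcript_id)]$fpkm
  keep <- !is_pseudo |
    (!is.na(pseudo_expr) & pseudo_expr >= med)
  targets <- sevenk[keep]
  if (nrow(targets) == 0L) return(factor_set("7SK.Binding", character(0)))
  peaks <- as.data.table(clip_peaks)[assay == "clip"]
  tgt <- targets[, .(transcript_id, region = "span", chrom, start, end, strand)]
  hits <- overlap_hits(tgt, peaks)
  factor_set("7SK.Binding", sort(unique(hits$factor_name)),
             provenance = "clip_overlap")
}

#' Split a factor set by sequence specificity
#'
#' @param fs a [factor_set()].
#' @param catalog character vector of sequence-specific factor names
#'   (flat input table; no live motif-database queries).
#' @return List with `sequence_specific` and `non_specific`
#'   [factor_set()]s forming a disjoint partition of `fs`.
#' @export
stratify_sequence_specific <- function(fs, catalog) {
  spec <- fs$members %in% catalog
  list(sequence_specific = factor_set(paste0(fs$name, ".seq_specific"),
                                      fs$members[spec]),
       non_specific = factor_set(paste0(fs$name, ".non_specific"),
                                 fs$members[!spec]))
}

#' Subset a feature matrix by factor set
#'
#' Retains the binding columns of member factors plus (by default) the
#' entire annotation block, as every subset model is always accompanied
#' by annotation and sequence features.
#'
#' @param fm a [assemble_matrix()] feature matrix.
#' @param fs a [factor_set()].
#' @param keep_annotation keep annotation columns (default `TRUE`).
#' @return A `feature_matrix` restricted to the selected columns; zero
#'   retained binding columns is an error.
#' @export
subset_matrix <- function(fm, fs, keep_annotation = TRUE) {
  keep <- (fm$meta$kind == "binding" & fm$meta$factor_name %in% fs$members) |
    (keep_annotation & fm$meta$kind == "annotation")
  if (!any(fm$meta$kind[keep] == "binding"))
    stop(sprintf("factor set '%s' selects no binding columns", fs$name))
  structure(list(X = fm$X[, fm$meta$name[keep], drop = FALSE],
                 meta = fm$meta[keep], polii = fm$polii),
            class = "feature_matrix")
}

#' Randomized baseline feature matrix
#'
#' Draws a factor count uniformly in `[1, n_factors]`, samples that many
#' factors without replacement, keeps only their binding columns, and
#' regenerates every retained binding entry as an independent
#' Bernoulli draw with that column's observed binding proportion.
#' Annotation columns are kept intact.
#'
#' @param fm a `feature_matrix`.
#' @param seed integer seed; fixed seed gives a bitwise-reproducible
#'   matrix.
#' @return A randomized `feature_matrix`.
#' @export
random_baseline_matrix <- function(fm, seed) {
  set.seed(seed)
  binding <- fm$meta[kind == "binding"]
  factors <- unique(binding$factor_name)
  n_keep <- sample.int(length(factors), 1L)
  kept <- sample(factors, n_keep)
  keep <- (fm$meta$kind == "binding" & fm$meta$factor_name %in% kept) |
    fm$meta$kind == "annotation"
  X <- fm$X[, fm$meta$name[keep], drop = FALSE]
  meta <- fm$meta[keep]
  n <- nrow(X)
  for (j in which(meta$kind == "binding"))
    X[, j] <- rbinom(n, 1L, meta$p_obs[j])
  structure(list(X = X, meta = meta, polii = fm$polii),
            class = "feature_matrix")
}
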