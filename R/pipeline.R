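#' End-to-end pipeline stages
#'
#' Two orchestration entry points: [run_genome_stage()] goes from genomes
#' (synthetic or on-disk) to annotated features, PULs, substrate
#' predictions and the substrate-labelled SusC/D reference (identity
#' matrices, NJ trees, clusters, congruence); [run_expression_stage()]
#' goes from spectral counts to placed, filtered, substrate-by-sample
#' %NSAF profiles. Both are deterministic given the configuration and
#' seed, and are the programmatic equivalents of the numbered analysis
#' scripts shipped with the package.
#'
#' @name pipeline
NULL

#' Run the genome stage
#'
#' @param generator a [generator_config()] for synthetic input, or NULL.
#' @param genome_inputs alternatively, a list of lists with paths `gff`,
#'   `faa`, `evidence` (all must exist before any stage runs).
#' @param annotation an [annotation_config()].
#' @param rules substrate rule table.
#' @param gap_tolerance,min_cazymes PUL detection parameters.
#' @param purity_threshold,min_size substrate-cluster extraction
#'   parameters.
#' @param build_trees build SusC/D identity matrices, NJ trees and
#'   clusters (requires >= 3 labelled proteins per class).
#' @param out_dir optional output directory for [write_outputs()].
#' @return List with `genomes`, `assignments` (per-genome), `puls`,
#'   `predictions`, `prediction_summary`, `summaries`, `reference`
#'   (labelled SusC/D proteins), `pul_index`, `identity_matrices`,
#'   `trees`, `clusters`, `congruence`, `truth` (synthetic only) and
#'   `manifest` (when written).
#' @export
run_genome_stage <- function(generator = NULL, genome_inputs = NULL,
                             annotation = annotation_config(),
                             rules = default_rule_table(),
                             gap_tolerance = 3L, min_cazymes = 2L,
                             purity_threshold = 0.8, min_size = 3L,
                             build_trees = TRUE, out_dir = NULL) {
  if (is.null(generator) && is.null(genome_inputs)) {
    stop("supply either a generator config or genome input paths",
         call. = FALSE)
  }
  truth <- NULL
  if (!is.null(generator)) {
    gen <- generate_genomes(generator)
    genomes <- lapply(gen$genomes, function(r) r$genome)
    evidences <- lapply(gen$genomes, function(r) r$evidence)
    truth <- dplyr::bind_rows(lapply(names(gen$genomes), function(g) {
      t <- gen$genomes[[g]]$truth
      if (nrow(t) > 0L) t$genome_id <- g
      t
    }))
  } else {
    # validate everything before running any stage
    for (gi in genome_inputs) {
      for (p in c(gi$gff, gi$faa, gi$evidence)) {
        if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
      }
    }
    genomes <- lapply(genome_inputs, function(gi) {
      read_genome(gi$gff, gi$faa, genome_id = gi$genome_id %||% NULL)
    })
    names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1L))
    evidences <- lapply(genome_inputs, function(gi) read_evidence(gi$evidence))
    names(evidences) <- names(genomes)
  }
  assignments <- lapply(evidences, assign_features, config = annotation)
  puls <- dplyr::bind_rows(lapply(names(genomes), function(g) {
    detect_puls(genomes[[g]], assignments[[g]], gap_tolerance, min_cazymes)
  }))
  class(puls) <- c("pul_table", class(puls))
  predictions <- classify_puls(puls, rules)
  prediction_summary <- summarize_predictions(predictions, length(genomes))
  summaries <- dplyr::bind_rows(lapply(names(genomes), function(g) {
    summarize_genome(genomes[[g]], assignments[[g]], puls)
  }))

  # labelled SusC/D reference over classified, tandem-complete PULs
  reference <- list(); pul_index <- list()
  gene_seq <- function(g, id) {
    gn <- genomes[[g]]$genes
    gn$protein_seq[match(id, gn$gene_id)]
  }
  for (i in seq_len(nrow(puls))) {
    pred <- predictions[predictions$pul_id == puls$pul_id[i], ]
    if (nrow(pred) == 0L || pred$substrate == "unclassified") next
    pairs <- puls$susCD_pairs[[i]]
    if (is.null(pairs) || nrow(pairs) == 0L) next
    g <- puls$genome_id[i]
    for (j in seq_len(nrow(pairs))) {
      reference[[length(reference) + 1L]] <- tibble::tibble(
        protein_id = c(pairs$susC[j], pairs$susD[j]),
        protein_class = c("susC_like", "susD_like"),
        substrate = pred$substrate, pul_id = puls$pul_id[i],
        genome_id = g,
        seq = c(gene_seq(g, pairs$susC[j]), gene_seq(g, pairs$susD[j])))
      pul_index[[length(pul_index) + 1L]] <- tibble::tibble(
        pul_id = puls$pul_id[i], susC = pairs$susC[j], susD = pairs$susD[j])
    }
  }
  reference <- dplyr::bind_rows(reference)
  pul_index <- dplyr::bind_rows(pul_index)

  identity_matrices <- list(); trees <- list(); clusters <- list()
  congruence <- NULL
  if (build_trees && nrow(reference) > 0L) {
    for (cls in c("susC_like", "susD_like")) {
      ref_c <- reference[reference$protein_class == cls, ]
      if (nrow(ref_c) < 3L) next
      seqs <- stats::setNames(ref_c$seq, ref_c$protein_id)
      labels <- stats::setNames(ref_c$substrate, ref_c$protein_id)
      key <- sub("_like$", "", cls)
      identity_matrices[[key]] <- build_identity_matrix(seqs)
      tr <- build_nj_tree(identity_matrices[[key]], leaf_labels = labels)
      trees[[key]] <- tr$tree
      clusters[[key]] <- extract_substrate_clusters(
        tr, purity_threshold = purity_threshold, min_size = min_size)
    }
    if (!is.null(clusters$susC) && !is.null(clusters$susD) &&
        nrow(pul_index) > 0L) {
      congruence <- suscd_congruence(clusters$susC$clusters,
                                     clusters$susD$clusters, pul_index)
    }
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    assignments_flat <- dplyr::bind_rows(lapply(names(assignments), function(g) {
      tb <- assignments_table(assignments[[g]])
      if (nrow(tb) > 0L) tb$genome_id <- g
      tb
    }))
    manifest <- write_outputs(list(
      puls = puls, predictions = predictions,
      assignments = assignments_flat, summaries = summaries,
      identity_matrices = identity_matrices, trees = trees), out_dir)
  }
  list(genomes = genomes, assignments = assignments, puls = puls,
       predictions = predictions, prediction_summary = prediction_summary,
       summaries = summaries, reference = reference, pul_index = pul_index,
       identity_matrices = identity_matrices, trees = trees,
       clusters = clusters, congruence = congruence, truth = truth,
       manifest = manifest)
}

#' Run the expression stage
#'
#' Consumes a labelled SusC/D reference (from [run_genome_stage()] or
#' user-provided) plus spectral counts, query sequences and sample
#' metadata; produces placed expression records and the
#' substrate-by-sample %NSAF profile.
#'
#' @param counts spectral-count tibble or TSV path.
#' @param queries tibble with `protein_id`, `protein_class`, `seq`.
#' @param metadata sample-metadata tibble or TSV path.
#' @param reference labelled reference tibble (`protein_id`,
#'   `protein_class`, `substrate`, `seq`).
#' @param identity_threshold placement identity cutoff (default 40).
#' @param min_pct_nsaf profile retention threshold (default 0.05).
#' @param bloom_thresholds chlorophyll thresholds for
#'   [assign_bloom_phase()].
#' @param identity_fun identity function passed to [place_expressed()].
#' @param out_dir optional output directory.
#' @return List with `expression` (per protein x sample records including
#'   placement), `placements`, `profile`, `metadata` (with phases),
#'   `manifest` (when written).
#' @export
run_expression_stage <- function(counts, queries, metadata, reference,
                                 identity_threshold = 40,
                                 min_pct_nsaf = 0.05,
                                 bloom_thresholds = c(2, 5),
                                 identity_fun = pairwise_identity,
                                 out_dir = NULL) {
  if (is.character(counts)) counts <- read_spectral_counts(counts)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  metadata <- assign_bloom_phase(metadata, bloom_thresholds)
  averaged <- average_technical_duplicates(counts)
  nsaf <- compute_pct_nsaf(averaged)
  query_seqs <- stats::setNames(queries$seq, queries$protein_id)
  ref_seqs <- stats::setNames(reference$seq, reference$protein_id)
  ref_subs <- stats::setNames(reference$substrate, reference$protein_id)
  placements <- place_expressed(query_seqs, ref_seqs, ref_subs,
                                identity_threshold = identity_threshold,
                                identity_fun = identity_fun)
  expression <- dplyr::inner_join(
    nsaf[nsaf$protein_id %in% queries$protein_id, ],
    placements, by = "protein_id")
  expression <- dplyr::left_join(
    expression, queries[, c("protein_id", "protein_class")],
    by = "protein_id")
  profile <- build_substrate_profile(expression, metadata,
                                     min_pct_nsaf = min_pct_nsaf)
  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_outputs(list(expression = expression,
                                   profile = profile$profile), out_dir)
  }
  list(expression = expression, placements = placements,
       profile = profile, metadata = metadata, manifest = manifest)
}
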