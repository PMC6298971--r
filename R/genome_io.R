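#' Read and validate genomes, evidence tables, count tables and metadata
#'
#' `genome_io` holds all file-format plumbing: GFF3 + protein FASTA in,
#' tab-separated evidence / spectral-count / metadata tables in, and all
#' tabular, JSON and Newick outputs back out. Internal gene coordinates are
#' 0-based half-open; external GFF3 stays 1-based inclusive.
#'
#' @name genome_io
NULL

#' Construct a genome object
#'
#' @param genome_id character scalar.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`, `protein_seq`, `length_aa`.
#' @param size_bp genome size in base pairs (> 0).
#' @return An object of class `pul_genome`: a list with elements
#'   `genome_id`, `genes` (tibble sorted by contig then start) and `size_bp`.
#' @export
new_genome <- function(genome_id, genes, size_bp) {
  genes <- tibble::as_tibble(genes)
  need <- c("gene_id", "contig_id", "start", "end", "strand",
            "protein_seq", "length_aa")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0L) {
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id in genome '", genome_id, "': ",
         paste(utils::head(dup, 3L), collapse = ", "), call. = FALSE)
  }
  if (any(genes$start < 0L) || any(genes$start >= genes$end)) {
    stop("gene coordinates must satisfy 0 <= start < end", call. = FALSE)
  }
  if (any(genes$length_aa < 1L) ||
      any(nchar(genes$protein_seq) != genes$length_aa)) {
    stop("protein_seq length must equal length_aa (>= 1)", call. = FALSE)
  }
  if (!is.numeric(size_bp) || size_bp <= 0) {
    stop("size_bp must be > 0", call. = FALSE)
  }
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  structure(list(genome_id = genome_id, genes = genes,
                 size_bp = as.numeric(size_bp)),
            class = "pul_genome")
}

#' @export
print.pul_genome <- function(x, ...) {
  cat("<pul_genome> ", x$genome_id, ": ", nrow(x$genes), " genes on ",
      length(unique(x$genes$contig_id)), " contig(s), ",
      format(x$size_bp, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Read a genome from GFF3 gene coordinates and a protein FASTA
#'
#' CDS features are matched to FASTA records by the GFF `ID` attribute,
#' falling back to `locus_tag`. GFF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. CDS features
#' without a protein sequence are dropped with a warning; the count of
#' dropped genes is attached as attribute `n_dropped`.
#'
#' @param gff_path path to a GFF3 file with CDS features.
#' @param faa_path path to the matching amino-acid FASTA.
#' @param genome_id genome identifier; default the GFF file stem.
#' @param size_bp genome size in bp; default: summed per-contig maximum
#'   gene end (contigs may be implicit in the GFF).
#' @return A `pul_genome` object (see [new_genome()]).
#' @export
read_genome <- function(gff_path, faa_path, genome_id = NULL, size_bp = NULL) {
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path, call. = FALSE)
  if (!file.exists(faa_path)) stop("FASTA file not found: ", faa_path, call. = FALSE)
  lines <- readLines(gff_path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1L))
  if (any(nf != 9L)) {
    stop("malformed GFF line ", body[which(nf != 9L)[1L]], " in ", gff_path,
         ": expected 9 tab-separated fields", call. = FALSE)
  }
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gff_path, call. = FALSE)
  ids <- as.character(gr$ID)
  if ("locus_tag" %in% names(S4Vectors::mcols(gr))) {
    lt <- as.character(gr$locus_tag)
    ids[is.na(ids)] <- lt[is.na(ids)]
  }
  if (anyNA(ids)) {
    stop("CDS feature without ID or locus_tag in ", gff_path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", gff_path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(faa_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  have <- ids %in% names(aa)
  n_dropped <- sum(!have)
  if (n_dropped > 0L) {
    warning(n_dropped, " CDS feature(s) lack a protein sequence and were dropped",
            call. = FALSE)
  }
  keep <- which(have)
  seqs <- as.character(aa[ids[keep]])
  genes <- tibble::tibble(
    gene_id = ids[keep],
    contig_id = as.character(GenomicRanges::seqnames(gr))[keep],
    start = GenomicRanges::start(gr)[keep] - 1L,  # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    protein_seq = unname(seqs),
    length_aa = nchar(unname(seqs))
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (is.null(size_bp)) {
    size_bp <- sum(tapply(genes$end, genes$contig_id, max))
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.gff3?$", "", basename(gff_path))
  }
  g <- new_genome(genome_id, genes, size_bp)
  attr(g, "n_dropped") <- n_dropped
  g
}

#' Write a genome back to GFF3 + protein FASTA
#'
#' Inverse of [read_genome()]: internal 0-based half-open coordinates are
#' serialized as 1-based inclusive GFF3 CDS features.
#'
#' @param genome a `pul_genome`.
#' @param gff_path,faa_path output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_genome <- function(genome, gff_path, faa_path) {
  genes <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "pulpredict"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  rtracklayer::export(gr, gff_path, format = "gff3")
  aa <- Biostrings::AAStringSet(stats::setNames(genes$protein_seq, genes$gene_id))
  Biostrings::writeXStringSet(aa, faa_path)
  invisible(c(gff_path, faa_path))
}

#' Read a domain-evidence table
#'
#' Expects a TSV with columns `gene_id`, `source`, `label`, `score`.
#' `source` must be one of pfam, dbcan, cazy_blast, tigrfam, sulfatlas,
#' merops. Score semantics are per source: bit score for HMM sources,
#' -log10 E-value for BLAST-type sources.
#'
#' @param tsv_path path to the evidence TSV.
#' @return A tibble of domain evidence.
#' @export
read_evidence <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("evidence file not found: ", tsv_path, call. = FALSE)
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    return(tibble::tibble(gene_id = character(), source = character(),
                          label = character(), score = numeric()))
  }
  need <- c("gene_id", "source", "label", "score")
  if (!all(need %in% names(df))) {
    stop("evidence table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$source), EVIDENCE_SOURCES)
  if (length(bad) > 0L) {
    stop("unknown evidence source(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(EVIDENCE_SOURCES, collapse = ", "),
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    stop("non-numeric score in evidence table at row ",
         which(is.na(score))[1L], call. = FALSE)
  }
  if (any(!nzchar(df$label))) stop("empty evidence label", call. = FALSE)
  tibble::tibble(gene_id = df$gene_id, source = df$source,
                 label = df$label, score = score)
}

#' Read a spectral-count table
#'
#' TSV columns: `protein_id`, `sample_id`, `replicate_id`, `spectral_count`,
#' `protein_length_aa`. The (protein, sample, replicate) triple must be
#' unique; counts are non-negative and lengths positive.
#'
#' @param tsv_path path to the count TSV.
#' @return A tibble of spectral-count records.
#' @export
read_spectral_counts <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("protein_id", "sample_id", "replicate_id",
            "spectral_count", "protein_length_aa")
  if (!all(need %in% names(df))) {
    stop("count table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$replicate_id <- as.character(df$replicate_id)
  if (any(df$spectral_count < 0)) stop("negative spectral_count", call. = FALSE)
  if (any(df$protein_length_aa < 1)) stop("protein_length_aa must be >= 1", call. = FALSE)
  key <- paste(df$protein_id, df$sample_id, df$replicate_id)
  if (anyDuplicated(key)) {
    stop("duplicate (protein_id, sample_id, replicate_id) record", call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' Read sample metadata
#'
#' TSV columns: `sample_id`, `date` (ISO-8601), optional `chlorophyll_a`
#' (ug/L) and optional `bloom_phase` (pre/early/mid/late).
#'
#' @param tsv_path path to the metadata TSV.
#' @return A tibble with parsed dates, ordered chronologically.
#' @export
read_sample_metadata <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "date") %in% names(df))) {
    stop("metadata must have columns sample_id, date", call. = FALSE)
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable ISO-8601 date at row ", which(is.na(d))[1L], call. = FALSE)
  }
  df$date <- d
  df$sample_id <- as.character(df$sample_id)
  if (!"chlorophyll_a" %in% names(df)) df$chlorophyll_a <- NA_real_
  if (!"bloom_phase" %in% names(df)) df$bloom_phase <- NA_character_
  bad <- setdiff(stats::na.omit(unique(df$bloom_phase)),
                 c("pre", "early", "mid", "late"))
  if (length(bad) > 0L) {
    stop("unknown bloom_phase value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$date, df$sample_id), , drop = FALSE]
  tibble::as_tibble(df[, c("sample_id", "date", "chlorophyll_a", "bloom_phase")])
}

# Serialize a PUL table (list-columns flattened) for TSV output.
flatten_pul_table <- function(puls) {
  tibble::tibble(
    pul_id = puls$pul_id,
    genome_id = puls$genome_id,
    contig_id = puls$contig_id,
    n_genes = puls$n_genes,
    completeness = puls$completeness,
    n_cazyme_genes = puls$n_cazyme_genes,
    n_sulfatases = puls$n_sulfatases,
    n_peptidases = puls$n_peptidases,
    has_susE = puls$has_susE,
    susCD_pairs = vapply(puls$susCD_pairs, function(p) {
      if (is.null(p) || nrow(p) == 0L) return("")
      paste(paste0(p$susC, ":", p$susD), collapse = ",")
    }, character(1L)),
    family_multiset = vapply(puls$family_multiset, function(m) {
      if (length(m) == 0L) return("")
      m <- m[order(names(m))]
      paste(paste0(names(m), ":", m), collapse = ",")
    }, character(1L)),
    gene_ids = vapply(puls$gene_ids, paste, character(1L), collapse = ",")
  )
}

#' Write pipeline outputs and return a manifest
#'
#' Accepts any subset of results and writes, with fixed column order,
#' deterministic sorting and 6-significant-digit floats: the PUL table
#' (TSV), substrate predictions (TSV + JSON), identity matrices (TSV),
#' trees (Newick), per-gene assignments (TSV) and expression profiles
#' (TSV). Re-running on identical inputs yields byte-identical files.
#'
#' @param results named list; recognized elements: `puls`, `predictions`,
#'   `assignments`, `identity_matrices` (named list of matrices), `trees`
#'   (named list of `phylo`), `expression`, `profile`, `summaries`.
#' @param out_dir output directory (created if needed).
#' @return A tibble manifest with one row per written file (`file`, `rows`).
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  manifest <- list()
  add <- function(file, rows) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(file = file, rows = rows)
  }
  if (!is.null(results$puls)) {
    p <- file.path(out_dir, "puls.tsv")
    flat <- flatten_pul_table(results$puls)
    write_tsv_stable(flat, p, sort_by = "pul_id")
    add("puls.tsv", nrow(flat))
  }
  if (!is.null(results$predictions)) {
    p <- file.path(out_dir, "substrate_predictions.tsv")
    write_tsv_stable(results$predictions, p, sort_by = "pul_id")
    add("substrate_predictions.tsv", nrow(results$predictions))
    pj <- file.path(out_dir, "substrate_predictions.json")
    df <- as.data.frame(results$predictions)
    df <- df[order(df$pul_id), , drop = FALSE]
    jsonlite::write_json(df, pj, dataframe = "rows", na = "null", digits = 6)
    add("substrate_predictions.json", nrow(df))
  }
  if (!is.null(results$assignments)) {
    p <- file.path(out_dir, "gene_assignments.tsv")
    write_tsv_stable(results$assignments, p, sort_by = "gene_id")
    add("gene_assignments.tsv", nrow(results$assignments))
  }
  for (nm in names(results$identity_matrices %||% list())) {
    m <- results$identity_matrices[[nm]]
    p <- file.path(out_dir, paste0("identity_", nm, ".tsv"))
    df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
    write_tsv_stable(df, p)
    add(basename(p), nrow(df))
  }
  for (nm in names(results$trees %||% list())) {
    p <- file.path(out_dir, paste0("tree_", nm, ".nwk"))
    ape::write.tree(results$trees[[nm]], p)
    add(basename(p), length(results$trees[[nm]]$tip.label))
  }
  if (!is.null(results$expression)) {
    p <- file.path(out_dir, "expression_records.tsv")
    write_tsv_stable(results$expression, p, sort_by = "protein_id")
    add("expression_records.tsv", nrow(results$expression))
  }
  if (!is.null(results$profile)) {
    p <- file.path(out_dir, "substrate_profile.tsv")
    write_tsv_stable(results$profile, p, sort_by = "substrate")
    add("substrate_profile.tsv", nrow(results$profile))
  }
  if (!is.null(results$summaries)) {
    p <- file.path(out_dir, "genome_summaries.tsv")
    write_tsv_stable(results$summaries, p, sort_by = "genome_id")
    add("genome_summaries.tsv", nrow(results$summaries))
  }
  manifest <- dplyr::bind_rows(manifest)
  write_tsv_stable(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
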