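#' Detect polysaccharide utilization loci along contigs
#'
#' A PUL is a contiguous cluster of signature genes — consensus CAZymes,
#' sulfatases, SusC/SusD-like transporters or generic TBDTs — separated by
#' at most `gap_tolerance` non-signature genes. A candidate cluster
#' qualifies as a PUL when it contains at least `min_cazymes` CAZyme genes,
#' or at least one CAZyme gene together with an adjacent susC-susD pair.
#' Clusters with a transporter tandem but no CAZyme gene are not PULs.
#'
#' @name pul_detection
NULL

# Pair each susC with the nearest unpaired susD within <= 1 intervening
# gene (strand ignored); greedy left to right on contig gene order.
pair_susCD <- function(idx_susC, idx_susD, gene_ids) {
  pairs <- list()
  free_d <- idx_susD
  for (c_i in sort(idx_susC)) {
    if (length(free_d) == 0L) break
    d <- abs(free_d - c_i)
    ok <- which(d <= 2L)
    if (length(ok) > 0L) {
      pick <- free_d[ok[which.min(d[ok])]]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        susC = gene_ids[c_i], susD = gene_ids[pick],
        susC_idx = c_i, susD_idx = pick)
      free_d <- setdiff(free_d, pick)
    }
  }
  if (length(pairs) == 0L) {
    tibble::tibble(susC = character(), susD = character(),
                   susC_idx = integer(), susD_idx = integer())
  } else {
    dplyr::bind_rows(pairs)
  }
}

#' Classify PUL completeness
#'
#' `complete` when the cluster carries at least one adjacent susC-susD
#' pair; `no_susD` when a SusC-like gene is present without a paired SusD;
#' `tbdt_only` when only a generic TBDT (too dissimilar to be SusC-like)
#' is present; `no_susCD` when the transporter tandem is missing entirely.
#'
#' @param n_pairs number of adjacent susC-susD pairs in the cluster.
#' @param n_susC number of susC genes in the cluster.
#' @param n_tbdt number of generic (non-susC) TBDT genes in the cluster.
#' @return One of `"complete"`, `"no_susD"`, `"tbdt_only"`, `"no_susCD"`.
#' @export
classify_completeness <- function(n_pairs, n_susC, n_tbdt) {
  if (n_pairs >= 1L) "complete"
  else if (n_susC >= 1L) "no_susD"
  else if (n_tbdt >= 1L) "tbdt_only"
  else "no_susCD"
}

#' Detect PULs in an annotated genome
#'
#' Scans each contig left to right, groups signature genes into maximal
#' runs separated by at most `gap_tolerance` non-signature genes, and
#' emits qualifying clusters as PULs. Intervening non-signature genes
#' inside the cluster span are included as member genes. The gene directly
#' downstream of a paired susD that carries no other annotation is flagged
#' as a putative susE-like gene.
#'
#' @param genome a `pul_genome`.
#' @param assignments a `feature_assignments` for this genome's genes.
#' @param gap_tolerance maximum number of consecutive non-signature genes
#'   bridged inside one cluster (default 3).
#' @param min_cazymes minimum CAZyme genes for a cluster without a susCD
#'   pair to qualify (default 2).
#' @return A tibble of class `pul_table`, one row per PUL: `pul_id`,
#'   `genome_id`, `contig_id`, `gene_ids` (list), `n_genes`,
#'   `susCD_pairs` (list of tibbles), `has_susE`, `susE_genes` (list),
#'   `completeness`, `family_multiset` (list of named integer vectors),
#'   `n_cazyme_genes`, `n_sulfatases`, `n_peptidases`, `start`, `end`.
#' @export
detect_puls <- function(genome, assignments, gap_tolerance = 3L,
                        min_cazymes = 2L) {
  stopifnot(gap_tolerance >= 0L, min_cazymes >= 1L)
  genes <- genome$genes
  fam <- assignments$families
  rol <- assignments$roles
  fam_by_gene <- split(fam$family, fam$gene_id)
  role_of <- function(role) unique(rol$gene_id[rol$role == role])
  susC_set <- role_of("susC")
  susD_set <- role_of("susD")
  tbdt_set <- role_of("tbdt_non_susC")
  sulf_set <- role_of("sulfatase")
  pept_set <- role_of("peptidase")
  susE_set <- role_of("susE_like")

  out <- list()
  ordinal <- 0L
  for (contig in unique(genes$contig_id)) {
    cg <- genes[genes$contig_id == contig, , drop = FALSE]
    ids <- cg$gene_id
    is_caz <- ids %in% names(fam_by_gene)
    signature <- is_caz | ids %in% susC_set | ids %in% susD_set |
      ids %in% tbdt_set | ids %in% sulf_set
    sig_idx <- which(signature)
    if (length(sig_idx) == 0L) next
    breaks <- which(diff(sig_idx) - 1L > gap_tolerance)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(sig_idx))
    for (k in seq_along(starts)) {
      span <- sig_idx[starts[k]]:sig_idx[ends[k]]
      mem <- ids[span]
      n_caz <- sum(mem %in% names(fam_by_gene))
      idx_c <- span[ids[span] %in% susC_set]
      idx_d <- span[ids[span] %in% susD_set]
      pairs <- pair_susCD(idx_c, idx_d, ids)
      qualifies <- n_caz >= min_cazymes || (n_caz >= 1L && nrow(pairs) >= 1L)
      if (!qualifies) next
      # putative susE: gene right after a paired susD with no annotation
      susE_genes <- intersect(mem, susE_set)
      if (nrow(pairs) > 0L) {
        for (d_i in pairs$susD_idx) {
          nxt <- d_i + 1L
          if (nxt <= max(span)) {
            g <- ids[nxt]
            if (g %in% mem && !(g %in% names(fam_by_gene)) &&
                !(g %in% c(susC_set, susD_set, tbdt_set, sulf_set, pept_set))) {
              susE_genes <- union(susE_genes, g)
            }
          }
        }
      }
      fam_counts <- table(unlist(fam_by_gene[intersect(mem, names(fam_by_gene))],
                                 use.names = FALSE))
      multiset <- stats::setNames(as.integer(fam_counts), names(fam_counts))
      ordinal <- ordinal + 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        pul_id = sprintf("%s_PUL%03d", genome$genome_id, ordinal),
        genome_id = genome$genome_id,
        contig_id = contig,
        gene_ids = list(mem),
        n_genes = length(mem),
        susCD_pairs = list(pairs[, c("susC", "susD"), drop = FALSE]),
        has_susE = length(susE_genes) > 0L,
        susE_genes = list(susE_genes),
        completeness = classify_completeness(nrow(pairs), length(idx_c),
                                             sum(mem %in% tbdt_set)),
        family_multiset = list(multiset),
        n_cazyme_genes = n_caz,
        n_sulfatases = sum(mem %in% sulf_set),
        n_peptidases = sum(mem %in% pept_set),
        start = min(cg$start[span]),
        end = max(cg$end[span])
      )
    }
  }
  res <- if (length(out) == 0L) {
    tibble::tibble(
      pul_id = character(), genome_id = character(), contig_id = character(),
      gene_ids = list(), n_genes = integer(), susCD_pairs = list(),
      has_susE = logical(), susE_genes = list(), completeness = character(),
      family_multiset = list(), n_cazyme_genes = integer(),
      n_sulfatases = integer(), n_peptidases = integer(),
      start = integer(), end = integer())
  } else {
    dplyr::bind_rows(out)
  }
  class(res) <- c("pul_table", class(res))
  res
}
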