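#' Consensus functional annotation of genes
#'
#' Derives per-gene feature assignments from raw domain evidence. CAZyme
#' families are called by a consensus vote: a family is accepted only when
#' at least two of the three CAZyme sources (Pfam HMM, dbCAN HMM, CAZy
#' BLAST) report it at or above the per-source score threshold. SusC-like
#' transporters are called from the TIGR04056 model, SusD-like lipoproteins
#' from Pfam models PF12741/PF12771/PF14322; sulfatases from SulfAtlas hits
#' and peptidases from MEROPS hits.
#'
#' @name feature_annotation
NULL

#' Annotation configuration
#'
#' Per-source acceptance thresholds and role-detection label lists. HMM
#' sources are thresholded on bit score (default >= 25 bits); BLAST-type
#' sources on -log10 E-value (default >= 4, i.e. E <= 1e-4, the MEROPS
#' default). These defaults stand in for family-specific cutoffs and are
#' fully configurable.
#'
#' @param thresholds named numeric vector of per-source score thresholds.
#' @param susc_model TIGRfam label identifying SusC-like TBDTs.
#' @param susd_models Pfam labels identifying SusD-like proteins.
#' @param tbdt_labels generic TBDT evidence labels (TBDT hit without the
#'   SusC model yields role `tbdt_non_susC`).
#' @param suse_labels evidence labels for susE-like genes. Default empty:
#'   the source gives no susE model, so susE is only called positionally
#'   (and flagged putative) during PUL detection.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(
    thresholds = c(pfam = 25, dbcan = 25, tigrfam = 25, sulfatlas = 25,
                   cazy_blast = 4, merops = 4),
    susc_model = "TIGR04056",
    susd_models = c("PF12741", "PF12771", "PF14322"),
    tbdt_labels = c("PF00593", "PF07715"),
    suse_labels = character()) {
  stopifnot(all(EVIDENCE_SOURCES %in% names(thresholds)))
  structure(list(thresholds = thresholds, susc_model = susc_model,
                 susd_models = susd_models, tbdt_labels = tbdt_labels,
                 suse_labels = suse_labels),
            class = "annotation_config")
}

#' Normalize a CAZy-style family label to its parent family
#'
#' Subfamily suffixes (e.g. `GH5_4`) are reduced to the parent family
#' (`GH5`) for rule matching; non-CAZy labels pass through unchanged.
#'
#' @param label character vector of family labels.
#' @return Character vector of normalized labels.
#' @export
normalize_family <- function(label) {
  ifelse(grepl(CAZY_FAMILY_RE, label),
         regmatches(label, regexpr(CAZY_FAMILY_RE, label)),
         label)
}

#' Consensus CAZyme family assignment
#'
#' A family is assigned to a gene iff at least two distinct sources among
#' pfam, dbcan and cazy_blast report that (normalized) family at or above
#' the source threshold. A gene may carry several families (e.g. a GH plus
#' a CBM); each family votes independently.
#'
#' @param evidence tibble of domain evidence (see [read_evidence()]).
#' @param config an [annotation_config()].
#' @return Tibble with columns `gene_id`, `family` (normalized),
#'   `family_raw` (verbatim labels, comma-joined), `sources`
#'   (comma-joined supporting sources), `n_sources`.
#' @export
assign_cazyme_families <- function(evidence, config = annotation_config()) {
  caz_sources <- c("pfam", "dbcan", "cazy_blast")
  ev <- evidence[evidence$source %in% caz_sources &
                   grepl(CAZY_FAMILY_RE, evidence$label), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(tibble::tibble(gene_id = character(), family = character(),
                          family_raw = character(), sources = character(),
                          n_sources = integer()))
  }
  ev <- ev[ev$score >= config$thresholds[ev$source], , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(tibble::tibble(gene_id = character(), family = character(),
                          family_raw = character(), sources = character(),
                          n_sources = integer()))
  }
  ev$family <- normalize_family(ev$label)
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$gene_id, .data$family),
    family_raw = paste(sort(unique(.data$label)), collapse = ","),
    sources = paste(sort(unique(.data$source)), collapse = ","),
    n_sources = dplyr::n_distinct(.data$source),
    .groups = "drop"
  )
  out <- out[out$n_sources >= 2L, , drop = FALSE]
  dplyr::arrange(out, .data$gene_id, .data$family)
}

#' Detect SusC/SusD and other roles from domain evidence
#'
#' Role calls per gene: `susC` iff the TIGR04056 model hits at or above
#' threshold; `susD` iff any of PF12741/PF12771/PF14322 hits; when both hit
#' one gene the role with the higher score/threshold ratio wins and the
#' conflict is reported via a message (susC and susD are mutually
#' exclusive). `tbdt_non_susC` marks generic TBDT evidence without the SusC
#' model; `sulfatase` any SulfAtlas hit (subfamily recorded in `label`);
#' `peptidase` any MEROPS hit; `susE_like` any configured susE label.
#'
#' @inheritParams assign_cazyme_families
#' @return Tibble with columns `gene_id`, `role`, `label` (the evidence
#'   label behind the call, e.g. the sulfatase subfamily).
#' @export
detect_sus_components <- function(evidence, config = annotation_config()) {
  thr <- config$thresholds
  ev <- evidence[evidence$score >= thr[evidence$source], , drop = FALSE]
  rows <- list()
  susc_genes <- unique(ev$gene_id[ev$source == "tigrfam" &
                                    ev$label == config$susc_model])
  susd_genes <- unique(ev$gene_id[ev$source == "pfam" &
                                    ev$label %in% config$susd_models])
  both <- intersect(susc_genes, susd_genes)
  if (length(both) > 0L) {
    for (g in both) {
      sc <- max(ev$score[ev$gene_id == g & ev$source == "tigrfam" &
                           ev$label == config$susc_model] / thr["tigrfam"])
      sd <- max(ev$score[ev$gene_id == g & ev$source == "pfam" &
                           ev$label %in% config$susd_models] / thr["pfam"])
      message("gene ", g, ": susC and susD evidence conflict; keeping ",
              if (sc >= sd) "susC" else "susD")
      if (sc >= sd) susd_genes <- setdiff(susd_genes, g)
      else susc_genes <- setdiff(susc_genes, g)
    }
  }
  if (length(susc_genes) > 0L) {
    rows$susC <- tibble::tibble(gene_id = susc_genes, role = "susC",
                                label = config$susc_model)
  }
  if (length(susd_genes) > 0L) {
    sd_ev <- ev[ev$gene_id %in% susd_genes & ev$source == "pfam" &
                  ev$label %in% config$susd_models, ]
    lab <- tapply(sd_ev$label, sd_ev$gene_id, function(x) x[1L])
    rows$susD <- tibble::tibble(gene_id = names(lab), role = "susD",
                                label = unname(lab))
  }
  tb <- ev[ev$label %in% config$tbdt_labels, , drop = FALSE]
  tb_genes <- setdiff(unique(tb$gene_id), susc_genes)
  if (length(tb_genes) > 0L) {
    rows$tbdt <- tibble::tibble(gene_id = tb_genes, role = "tbdt_non_susC",
                                label = "TBDT")
  }
  if (length(config$suse_labels) > 0L) {
    se_genes <- unique(ev$gene_id[ev$label %in% config$suse_labels])
    if (length(se_genes) > 0L) {
      rows$susE <- tibble::tibble(gene_id = se_genes, role = "susE_like",
                                  label = "susE")
    }
  }
  su <- ev[ev$source == "sulfatlas", , drop = FALSE]
  if (nrow(su) > 0L) {
    lab <- tapply(su$label, su$gene_id, function(x) x[1L])
    rows$sulf <- tibble::tibble(gene_id = names(lab), role = "sulfatase",
                                label = unname(lab))
  }
  pe <- ev[ev$source == "merops", , drop = FALSE]
  if (nrow(pe) > 0L) {
    lab <- tapply(pe$label, pe$gene_id, function(x) x[1L])
    rows$pept <- tibble::tibble(gene_id = names(lab), role = "peptidase",
                                label = unname(lab))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(gene_id = character(), role = character(),
                          label = character()))
  }
  dplyr::arrange(out, .data$gene_id, .data$role)
}

#' Full per-gene feature assignment
#'
#' Bundles consensus CAZyme families and role calls into one object used
#' by PUL detection and genome summaries.
#'
#' @inheritParams assign_cazyme_families
#' @return List of class `feature_assignments` with tibbles `families` and
#'   `roles`, plus the `config` used.
#' @export
assign_features <- function(evidence, config = annotation_config()) {
  structure(list(families = assign_cazyme_families(evidence, config),
                 roles = detect_sus_components(evidence, config),
                 config = config),
            class = "feature_assignments")
}

#' @export
print.feature_assignments <- function(x, ...) {
  cat("<feature_assignments> ", dplyr::n_distinct(x$families$gene_id),
      " CAZyme gene(s), ", nrow(x$roles), " role call(s)\n", sep = "")
  invisible(x)
}

# Flat per-gene table for output.
assignments_table <- function(assignments) {
  fam <- assignments$families
  rol <- assignments$roles
  fam_flat <- if (nrow(fam) > 0L) {
    dplyr::summarise(dplyr::group_by(fam, .data$gene_id),
                     cazyme_families = paste(.data$family, collapse = ","),
                     .groups = "drop")
  } else tibble::tibble(gene_id = character(), cazyme_families = character())
  rol_flat <- if (nrow(rol) > 0L) {
    dplyr::summarise(dplyr::group_by(rol, .data$gene_id),
                     roles = paste(.data$role, collapse = ","),
                     role_labels = paste(.data$label, collapse = ","),
                     .groups = "drop")
  } else tibble::tibble(gene_id = character(), roles = character(),
                        role_labels = character())
  dplyr::full_join(fam_flat, rol_flat, by = "gene_id")
}

#' Genome-level feature summary
#'
#' Degradative CAZymes are genes carrying at least one GH, PL or CE family
#' (CBM-only and AA-only genes bind or assist but do not cleave). The
#' peptidase:CAZyme ratio is reported as NA when the genome has no
#' degradative CAZymes.
#'
#' @param genome a `pul_genome`.
#' @param assignments a `feature_assignments`.
#' @param puls optional PUL table from [detect_puls()]; fills `n_puls`.
#' @return One-row tibble: `genome_id`, `n_genes`, `n_degradative_cazymes`,
#'   `degradative_cazymes_per_mbp`, `n_sulfatases`, `n_peptidases`,
#'   `peptidase_cazyme_ratio`, `n_puls`.
#' @export
summarize_genome <- function(genome, assignments, puls = NULL) {
  if (genome$size_bp <= 0) stop("size_bp must be > 0", call. = FALSE)
  fam <- assignments$families
  degr_genes <- unique(fam$gene_id[grepl("^(GH|PL|CE)[0-9]+$", fam$family)])
  n_degr <- length(degr_genes)
  rol <- assignments$roles
  n_sulf <- sum(rol$role == "sulfatase")
  n_pept <- sum(rol$role == "peptidase")
  tibble::tibble(
    genome_id = genome$genome_id,
    n_genes = nrow(genome$genes),
    n_degradative_cazymes = n_degr,
    degradative_cazymes_per_mbp = n_degr / (genome$size_bp / 1e6),
    n_sulfatases = n_sulf,
    n_peptidases = n_pept,
    peptidase_cazyme_ratio = if (n_degr > 0L) n_pept / n_degr else NA_real_,
    n_puls = if (is.null(puls)) NA_integer_
             else sum(puls$genome_id == genome$genome_id)
  )
}
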