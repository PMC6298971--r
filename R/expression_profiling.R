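#' %NSAF expression profiling of SusC/D homologs
#'
#' Turns spectral counts into normalized spectral abundance factors
#' (%NSAF), places expressed SusC/D homologs onto the substrate-labelled
#' reference set by pairwise identity, filters by expression level and
#' produces substrate-by-sample temporal profiles across bloom phases.
#'
#' @name expression_profiling
NULL

#' Average technical duplicates
#'
#' Arithmetic mean of spectral counts over replicate ids per (protein,
#' sample). A missing replicate is treated as absent: the mean is over the
#' replicates actually present, and the replicate count is reported.
#'
#' @param counts tibble of spectral-count records
#'   (see [read_spectral_counts()]).
#' @return Tibble: `protein_id`, `sample_id`, `spectral_count` (mean),
#'   `protein_length_aa`, `n_replicates`.
#' @export
average_technical_duplicates <- function(counts) {
  dplyr::summarise(
    dplyr::group_by(counts, .data$protein_id, .data$sample_id),
    spectral_count = mean(.data$spectral_count),
    protein_length_aa = .data$protein_length_aa[1L],
    n_replicates = dplyr::n(),
    .groups = "drop")
}

#' Compute %NSAF per sample
#'
#' Within each sample, `NSAF_i = (SpC_i / L_i) / sum_k (SpC_k / L_k)` and
#' `%NSAF = 100 x NSAF`. A %NSAF of 1 therefore corresponds to 1% of all
#' length-adjusted spectral counts in that sample. The normalizer runs
#' over every protein in the sample's table, so per-sample %NSAF sums to
#' 100 before any filtering. Proteins with zero counts get %NSAF 0.
#'
#' @param counts tibble with `protein_id`, `sample_id`, `spectral_count`
#'   (replicate-averaged) and `protein_length_aa`.
#' @return The input with an added `pct_nsaf` column.
#' @export
compute_pct_nsaf <- function(counts) {
  stopifnot(all(counts$protein_length_aa >= 1))
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$sample_id),
    .saf = .data$spectral_count / .data$protein_length_aa,
    .total = sum(.data$.saf))
  if (any(out$.total <= 0)) {
    bad <- unique(out$sample_id[out$.total <= 0])
    stop("sample(s) with all-zero spectral counts (normalizer undefined): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(out, pct_nsaf = 100 * .data$.saf / .data$.total)
  out <- dplyr::ungroup(out)
  out$.saf <- NULL
  out$.total <- NULL
  out
}

#' Place expressed query proteins onto the labelled reference set
#'
#' Each query is compared to every reference by pairwise identity; the
#' best-scoring reference wins. If the best identity, rounded to 0.1,
#' reaches `identity_threshold` the query inherits the reference PUL's
#' predicted substrate. Ties at the best identity inherit the shared
#' substrate when all tied references agree, otherwise the query is
#' marked ambiguous. Below the threshold the query stays unclassified.
#'
#' @param query_seqs named character vector of expressed protein sequences.
#' @param reference_seqs named character vector of reference sequences.
#' @param reference_substrates named character vector mapping reference
#'   ids to substrate labels.
#' @param identity_threshold percent identity cutoff (default 40,
#'   compared as `>=` on the value rounded to 0.1).
#' @param identity_fun identity function (default [pairwise_identity()]).
#' @return Tibble: `protein_id`, `placed_reference`, `placement_identity`
#'   (rounded to 0.1), `inherited_substrate` (NA when unclassified or
#'   ambiguous), `status` (`placed`/`ambiguous`/`unclassified`).
#' @export
place_expressed <- function(query_seqs, reference_seqs, reference_substrates,
                            identity_threshold = 40,
                            identity_fun = pairwise_identity) {
  if (length(reference_seqs) == 0L) {
    stop("empty reference set", call. = FALSE)
  }
  stopifnot(!is.null(names(query_seqs)), !is.null(names(reference_seqs)),
            all(names(reference_seqs) %in% names(reference_substrates)))
  rows <- lapply(names(query_seqs), function(q) {
    idents <- vapply(reference_seqs, function(r) identity_fun(query_seqs[[q]], r),
                     numeric(1L))
    idents <- round(idents, 1L)
    best <- max(idents)
    if (best >= identity_threshold) {
      tied <- names(reference_seqs)[idents == best]
      subs <- unique(unname(reference_substrates[tied]))
      if (length(subs) == 1L) {
        tibble::tibble(protein_id = q, placed_reference = tied[1L],
                       placement_identity = best,
                       inherited_substrate = subs, status = "placed")
      } else {
        tibble::tibble(protein_id = q, placed_reference = tied[1L],
                       placement_identity = best,
                       inherited_substrate = NA_character_,
                       status = "ambiguous")
      }
    } else {
      tibble::tibble(protein_id = q, placed_reference = NA_character_,
                     placement_identity = best,
                     inherited_substrate = NA_character_,
                     status = "unclassified")
    }
  })
  dplyr::bind_rows(rows)
}

#' Assign bloom phases from chlorophyll a
#'
#' Explicit `bloom_phase` labels in the metadata pass through unchanged.
#' Otherwise phases are assigned from the chlorophyll a series and date
#' order: samples at or before the chlorophyll peak are `pre` (below
#' `t1`), `early` (between `t1` and `t2`) or `mid` (at or above `t2`);
#' samples after the peak are `mid` while chlorophyll stays at or above
#' `t2` and `late` once it falls below. A series that never reaches `t1`
#' is entirely pre-bloom.
#'
#' @param metadata tibble from [read_sample_metadata()].
#' @param thresholds numeric `c(t1, t2)` in ug/L chlorophyll a
#'   (default `c(2, 5)`).
#' @return The metadata with `bloom_phase` filled in.
#' @export
assign_bloom_phase <- function(metadata, thresholds = c(2, 5)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  if (all(!is.na(metadata$bloom_phase))) return(metadata)
  if (anyNA(metadata$chlorophyll_a)) {
    stop("cannot assign bloom phases: chlorophyll_a missing and no ",
         "explicit bloom_phase labels supplied", call. = FALSE)
  }
  md <- metadata[order(metadata$date), , drop = FALSE]
  chl <- md$chlorophyll_a
  t1 <- thresholds[1]; t2 <- thresholds[2]
  if (max(chl) < t1) {
    md$bloom_phase <- "pre"
    return(md)
  }
  peak <- which.max(chl)
  phase <- character(length(chl))
  for (i in seq_along(chl)) {
    if (i <= peak) {
      phase[i] <- if (chl[i] < t1) "pre" else if (chl[i] < t2) "early" else "mid"
    } else {
      phase[i] <- if (chl[i] >= t2) "mid" else "late"
    }
  }
  # explicit user-supplied labels override the derived ones
  md$bloom_phase <- ifelse(is.na(md$bloom_phase), phase, md$bloom_phase)
  md
}

#' Build a substrate-by-sample expression profile
#'
#' Placed proteins are grouped per protein id; a group is retained iff its
#' maximum %NSAF over samples reaches `min_pct_nsaf`. Retained %NSAF is
#' summed per (substrate, sample, protein class), with SusC-like and
#' SusD-like proteins always kept separate. Per-protein records are also
#' returned so individual homologs remain inspectable.
#'
#' @param expression tibble with `protein_id`, `sample_id`, `pct_nsaf`,
#'   `protein_class` (`susC_like`/`susD_like`/`other`) and
#'   `inherited_substrate` (NA rows are dropped).
#' @param metadata sample metadata with `bloom_phase` (see
#'   [assign_bloom_phase()]).
#' @param min_pct_nsaf retention threshold on a protein's maximum %NSAF
#'   (default 0.05, compared as `>=`).
#' @return List: `profile` (tibble `substrate` x `sample_id` with summed
#'   `pct_nsaf` per `protein_class`, `date`, `bloom_phase`), `retained`
#'   (per-protein records kept), `dropped_proteins` (ids filtered out).
#' @export
build_substrate_profile <- function(expression, metadata,
                                    min_pct_nsaf = 0.05) {
  expr <- expression[!is.na(expression$inherited_substrate), , drop = FALSE]
  if (nrow(expr) == 0L) {
    return(list(profile = tibble::tibble(substrate = character(),
                                         protein_class = character(),
                                         sample_id = character(),
                                         pct_nsaf = numeric(),
                                         date = as.Date(character()),
                                         bloom_phase = character()),
                retained = expr, dropped_proteins = character()))
  }
  peak <- dplyr::summarise(dplyr::group_by(expr, .data$protein_id),
                           max_nsaf = max(.data$pct_nsaf), .groups = "drop")
  keep_ids <- peak$protein_id[peak$max_nsaf >= min_pct_nsaf]
  dropped <- setdiff(peak$protein_id, keep_ids)
  retained <- expr[expr$protein_id %in% keep_ids, , drop = FALSE]
  prof <- dplyr::summarise(
    dplyr::group_by(retained, .data$inherited_substrate,
                    .data$protein_class, .data$sample_id),
    pct_nsaf = sum(.data$pct_nsaf), .groups = "drop")
  names(prof)[names(prof) == "inherited_substrate"] <- "substrate"
  prof <- dplyr::left_join(prof,
                           metadata[, c("sample_id", "date", "bloom_phase")],
                           by = "sample_id")
  prof <- dplyr::arrange(prof, .data$substrate, .data$protein_class,
                         .data$date, .data$sample_id)
  list(profile = prof, retained = retained, dropped_proteins = dropped)
}
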