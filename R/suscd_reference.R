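#' Substrate-labelled SusC/D reference trees
#'
#' Pairwise global-alignment identities among PUL-associated SusC-like and
#' SusD-like proteins, neighbor-joining trees on the identity-derived
#' distances, extraction of substrate-pure clades, and SusC-SusD cluster
#' congruence.
#'
#' @name suscd_reference
NULL

#' Percent identity from global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1). Identity is 100 x matches / alignment columns,
#' gaps included in the denominator. The computation is symmetric in its
#' arguments (sequences are ordered canonically before alignment).
#'
#' @param seq_a,seq_b amino-acid strings (20 IUPAC letters plus X).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, gap_opening = 11,
                              gap_extension = 1) {
  validate_protein(seq_a, "seq_a")
  validate_protein(seq_b, "seq_b")
  if (seq_b < seq_a) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / ncol_aln
}

#' Pairwise identity matrix over a sequence set
#'
#' Each unordered pair is aligned once; the diagonal is 100.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param identity_fun identity function taking two sequences; default
#'   [pairwise_identity()].
#' @return Symmetric numeric matrix of percent identities with sequence
#'   names as dimnames.
#' @export
build_identity_matrix <- function(sequences, identity_fun = pairwise_identity) {
  n <- length(sequences)
  ids <- names(sequences)
  if (n == 0L) return(matrix(numeric(), 0L, 0L))
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique names", call. = FALSE)
  }
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- identity_fun(sequences[[i]], sequences[[j]])
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Neighbor-joining tree from an identity matrix
#'
#' Distances are `d = 1 - identity/100` (uncorrected by default; a
#' Poisson correction `-log(identity/100)` is selectable). Negative
#' branch lengths produced by NJ are clamped to zero.
#'
#' @param identity_matrix symmetric percent-identity matrix.
#' @param leaf_labels optional named character vector mapping protein ids
#'   to substrate labels (kept alongside the tree).
#' @param correction `"none"` (default) or `"poisson"`.
#' @return A list of class `suscd_tree`: `tree` (an ape `phylo`) and
#'   `leaf_labels`.
#' @export
build_nj_tree <- function(identity_matrix, leaf_labels = NULL,
                          correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- nrow(identity_matrix)
  if (is.null(n) || n < 3L) {
    stop("neighbor joining needs >= 3 sequences; with fewer the topology ",
         "is trivial", call. = FALSE)
  }
  frac <- pmin(pmax(identity_matrix / 100, 1e-6), 1)
  d <- switch(correction, none = 1 - frac, poisson = -log(frac))
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  structure(list(tree = tree, leaf_labels = leaf_labels),
            class = "suscd_tree")
}

#' @export
print.suscd_tree <- function(x, ...) {
  cat("<suscd_tree> ", length(x$tree$tip.label), " leaves, ",
      sum(!is.na(x$leaf_labels %||% NA)), " labelled\n", sep = "")
  invisible(x)
}

# children adjacency list of a rooted phylo
tree_children <- function(tree) {
  kids <- vector("list", max(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2L])
  }
  kids
}

#' Extract substrate-pure clusters from a labelled tree
#'
#' The tree is midpoint-rooted and traversed from the root; a clade is
#' emitted as a substrate cluster when it has at least `min_size` leaves,
#' at least one labelled leaf, and its labelled-leaf majority substrate
#' reaches frequency `purity_threshold` (unlabelled leaves do not count
#' against purity). Emitted clades are maximal: their subclades are not
#' revisited. Leaves outside every cluster are reported as
#' heterogeneous/undefined.
#'
#' @param suscd_tree a `suscd_tree`, or an ape `phylo`.
#' @param leaf_labels named character vector id -> substrate (NA allowed);
#'   defaults to the labels stored in the tree object.
#' @param purity_threshold minimum majority frequency (default 0.8).
#' @param min_size minimum clade size in leaves (default 3).
#' @return List with `clusters` (tibble: `cluster_id`, `members` list,
#'   `n_members`, `n_labelled`, `majority_substrate`, `purity`) and
#'   `unassigned` (character vector of leaf ids).
#' @export
extract_substrate_clusters <- function(suscd_tree, leaf_labels = NULL,
                                       purity_threshold = 0.8,
                                       min_size = 3L) {
  tree <- if (inherits(suscd_tree, "suscd_tree")) suscd_tree$tree else suscd_tree
  if (is.null(leaf_labels) && inherits(suscd_tree, "suscd_tree")) {
    leaf_labels <- suscd_tree$leaf_labels
  }
  if (is.null(leaf_labels)) stop("leaf_labels required", call. = FALSE)
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  kids <- tree_children(rooted)
  tips_below <- vector("list", max(rooted$edge))
  fill_tips <- function(node) {
    if (node <= ntip) {
      tips_below[[node]] <<- rooted$tip.label[node]
    } else {
      for (ch in kids[[node]]) fill_tips(ch)
      tips_below[[node]] <<- unlist(tips_below[kids[[node]]])
    }
  }
  root <- ntip + 1L
  fill_tips(root)

  clusters <- list()
  visit <- function(node) {
    tips <- tips_below[[node]]
    labs <- leaf_labels[tips]
    labs <- labs[!is.na(labs)]
    if (length(tips) >= min_size && length(labs) > 0L) {
      tab <- sort(table(labs), decreasing = TRUE)
      purity <- as.numeric(tab[1L]) / length(labs)
      if (purity >= purity_threshold) {
        clusters[[length(clusters) + 1L]] <<- tibble::tibble(
          cluster_id = sprintf("cluster_%03d", length(clusters) + 1L),
          members = list(tips), n_members = length(tips),
          n_labelled = length(labs),
          majority_substrate = names(tab)[1L], purity = purity)
        return(invisible())  # maximal clade: do not descend
      }
    }
    if (node > ntip) for (ch in kids[[node]]) visit(ch)
    invisible()
  }
  visit(root)
  clusters <- if (length(clusters) == 0L) {
    tibble::tibble(cluster_id = character(), members = list(),
                   n_members = integer(), n_labelled = integer(),
                   majority_substrate = character(), purity = numeric())
  } else {
    dplyr::bind_rows(clusters)
  }
  assigned <- unlist(clusters$members)
  list(clusters = clusters,
       unassigned = setdiff(tree$tip.label, assigned))
}

#' SusC-SusD cluster congruence
#'
#' Over PULs whose SusC protein sits in some SusC substrate cluster and
#' whose SusD protein sits in some SusD substrate cluster, the fraction
#' for which the two clusters carry the same majority substrate. With no
#' eligible PUL the result is NA (not 0).
#'
#' @param susC_clusters,susD_clusters cluster tibbles from
#'   [extract_substrate_clusters()] (the `clusters` element).
#' @param pul_index tibble with columns `pul_id`, `susC`, `susD` (protein
#'   ids of each PUL's transporter pair).
#' @return List: `fraction` (numeric or NA), `n_eligible`, `n_congruent`.
#' @export
suscd_congruence <- function(susC_clusters, susD_clusters, pul_index) {
  member_map <- function(clusters) {
    if (nrow(clusters) == 0L) return(character())
    ids <- unlist(clusters$members)
    subs <- rep(clusters$majority_substrate,
                vapply(clusters$members, length, integer(1L)))
    stats::setNames(subs, ids)
  }
  mc <- member_map(susC_clusters)
  md <- member_map(susD_clusters)
  eligible <- pul_index$susC %in% names(mc) & pul_index$susD %in% names(md)
  n_el <- sum(eligible)
  if (n_el == 0L) {
    return(list(fraction = NA_real_, n_eligible = 0L, n_congruent = 0L))
  }
  cong <- mc[pul_index$susC[eligible]] == md[pul_index$susD[eligible]]
  list(fraction = sum(cong) / n_el, n_eligible = n_el,
       n_congruent = sum(cong))
}
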