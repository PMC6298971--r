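test_that("pairwise identity: exact match, single substitution, symmetry, input checks", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)

  a <- "ACDEFGHIKL"; b <- "ACDEFGHIKV"
  # DP oracle: the optimal global alignment is gapless, so identity = 9/10
  expect_equal(nw_affine_score(a, b), ungapped_score(a, b))
  expect_equal(pairwise_identity(a, b), 90)

  set.seed(3)
  for (i in 1:5) {
    x <- rand_aa(8); y <- rand_aa(8)
    v1 <- pairwise_identity(x, y)
    v2 <- pairwise_identity(y, x)
    expect_identical(v1, v2)
    expect_true(v1 >= 0 && v1 <= 100)
  }
  expect_error(pairwise_identity("", "ACD"), "non-empty")
  expect_error(pairwise_identity("AC1D", "ACD"), "non-amino-acid")
  expect_silent(pairwise_identity("ACXD", "ACDD"))  # X allowed
})

test_that("identity matrices are symmetric with unit diagonal and permute consistently", {
  seqs <- c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKV", s3 = "MNPQRSTVWY")
  m <- build_identity_matrix(seqs)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), c(s1 = 100, s2 = 100, s3 = 100))
  expect_equal(m, t(m))
  perm <- c("s3", "s1", "s2")
  m2 <- build_identity_matrix(seqs[perm])
  expect_equal(m2, m[perm, perm])
  expect_equal(dim(build_identity_matrix(character())), c(0L, 0L))
})

test_that("NJ recovers additive 4-taxon topologies found by exhaustive least squares", {
  topologies <- phangorn::allTrees(4, rooted = FALSE,
                                   tip.label = paste0("t", 1:4))
  designs <- lapply(topologies, path_design_matrix,
                    tip_order = paste0("t", 1:4))
  set.seed(21)
  for (rep in 1:10) {
    gen <- topologies[[sample(length(topologies), 1)]]
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(gen)[paste0("t", 1:4), paste0("t", 1:4)]
    idm <- 100 * (1 - D / max(D) * 0.9)  # map to identity scale
    nj_tr <- build_nj_tree(idm)$tree
    best <- ls_best_topology((1 - idm / 100), topologies, designs)
    expect_true(same_topology(nj_tr, best))
    expect_true(all(nj_tr$edge.length >= 0))
  }
})

test_that("degenerate tree inputs behave: <3 sequences error, duplicates sit as zero-length siblings", {
  expect_error(build_nj_tree(build_identity_matrix(
    c(a = "ACDEF", b = "ACDEF"))), "3 sequences")

  seqs <- c(a = "ACDEFGHIKLMNPQRSTVWY", b = "ACDEFGHIKLMNPQRSTVWY",
            c = "MNPQRSTVWYACDEFGHIKL", d = "WYACDEFGHIKLMNPQRSTV")
  tr <- build_nj_tree(build_identity_matrix(seqs))$tree
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(unname(cd["a", "b"]), 0)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
})

test_that("substrate clusters honor purity and size thresholds; unlabelled leaves do not dilute", {
  # a caterpillar with one pure clade and one mixed clade
  nwk <- "(((l1:0.01,l2:0.01):0.01,(l3:0.01,(l4:0.01,l5:0.01):0.01):0.01):0.3,((m1:0.01,m2:0.01):0.01,(m3:0.01,(m4:0.01,m5:0.01):0.01):0.01):0.3);"
  tree <- ape::read.tree(text = nwk)
  labels <- c(l1 = "laminarin", l2 = "laminarin", l3 = "laminarin",
              l4 = "laminarin", l5 = "laminarin",
              m1 = "alginate", m2 = "xylan", m3 = "laminarin",
              m4 = "alginate", m5 = "xylan")
  res <- extract_substrate_clusters(tree, labels, purity_threshold = 0.8,
                                    min_size = 3L)
  expect_equal(nrow(res$clusters), 1L)
  expect_equal(res$clusters$majority_substrate, "laminarin")
  expect_equal(res$clusters$purity, 1.0)
  expect_setequal(res$clusters$members[[1]], paste0("l", 1:5))
  expect_setequal(res$unassigned, paste0("m", 1:5))

  # 4 laminarin + 1 alginate at threshold 0.8: purity exactly 0.8
  labels2 <- labels
  labels2["l5"] <- "alginate"
  res2 <- extract_substrate_clusters(tree, labels2, purity_threshold = 0.8,
                                     min_size = 3L)
  cl <- res2$clusters[res2$clusters$majority_substrate == "laminarin", ]
  expect_equal(cl$purity[1], 0.8)

  # unlabelled leaves count toward size but not against purity
  labels3 <- labels
  labels3[c("l4", "l5")] <- NA
  res3 <- extract_substrate_clusters(tree, labels3, purity_threshold = 0.8,
                                     min_size = 3L)
  expect_true(any(res3$clusters$majority_substrate == "laminarin" &
                    res3$clusters$purity == 1.0))

  # fully mixed: no clusters
  labels4 <- stats::setNames(rep(c("a", "b"), 5), names(labels))
  labels4[] <- rep(c("alg", "xyl"), 5)
  res4 <- extract_substrate_clusters(tree, labels4, purity_threshold = 0.9,
                                     min_size = 3L)
  expect_equal(nrow(res4$clusters), 0L)
  expect_setequal(res4$unassigned, names(labels))
})

test_that("SusC-SusD congruence counts co-classified tandem pairs", {
  mk_clusters <- function(prefix, substrates) {
    tibble::tibble(
      cluster_id = paste0("c", seq_along(substrates)),
      members = lapply(seq_along(substrates), function(i) {
        paste0(prefix, (3 * i - 2):(3 * i))
      }),
      n_members = 3L, n_labelled = 3L,
      majority_substrate = substrates, purity = 1.0)
  }
  cc <- mk_clusters("C", c("laminarin", "alginate"))
  dd <- mk_clusters("D", c("laminarin", "alginate"))
  idx <- tibble::tibble(pul_id = paste0("p", 1:6),
                        susC = paste0("C", 1:6), susD = paste0("D", 1:6))
  expect_equal(suscd_congruence(cc, dd, idx)$fraction, 1.0)

  # move 3 SusD proteins into the wrong cluster: 7 of 10 congruent
  dd10 <- mk_clusters("D", c("laminarin", "alginate"))
  dd10$members <- list(paste0("D", c(1:3, 5:6, 8:9)), paste0("D", c(4, 7, 10)))
  dd10$n_members <- c(7L, 3L)
  idx10 <- tibble::tibble(pul_id = paste0("p", 1:10),
                          susC = paste0("C", c(1:6, 1:4)),
                          susD = paste0("D", 1:10))
  res <- suscd_congruence(cc, dd10, idx10)
  expect_equal(res$n_eligible, 10L)
  expect_equal(res$fraction, 0.7)

  # no eligible pairs: missing, not zero
  idx0 <- tibble::tibble(pul_id = "p1", susC = "CX", susD = "DX")
  expect_true(is.na(suscd_congruence(cc, dd, idx0)$fraction))
})
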