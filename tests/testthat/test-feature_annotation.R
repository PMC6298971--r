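test_that("CAZyme families need at least two supporting sources", {
  ev <- dplyr::bind_rows(
    caz_ev("g1", "GH13", c("pfam", "dbcan")),
    caz_ev("g2", "GH13", "dbcan"),
    caz_ev("g3", "GH16", c("pfam", "dbcan", "cazy_blast")),
    caz_ev("g3", "CBM6", c("pfam", "dbcan")))
  fam <- assign_cazyme_families(ev)
  expect_equal(fam$family[fam$gene_id == "g1"], "GH13")
  expect_false("g2" %in% fam$gene_id)           # single source fails
  expect_setequal(fam$family[fam$gene_id == "g3"], c("GH16", "CBM6"))
  expect_equal(fam$n_sources[fam$gene_id == "g3" & fam$family == "GH16"], 3L)
})

test_that("per-source thresholds gate the vote and subfamilies normalize", {
  ev <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", source = c("pfam", "dbcan"),
                   label = "GH13", score = c(60, 10)),     # dbcan below 25
    tibble::tibble(gene_id = "g2", source = c("pfam", "cazy_blast"),
                   label = c("GH5_4", "GH5_46"), score = c(60, 12)))
  fam <- assign_cazyme_families(ev)
  expect_false("g1" %in% fam$gene_id)  # only one source above threshold
  expect_equal(fam$family[fam$gene_id == "g2"], "GH5")  # normalized parent
  expect_match(fam$family_raw[fam$gene_id == "g2"], "GH5_4")
})

test_that("SusC/D and other roles are detected from the prescribed models", {
  ev <- dplyr::bind_rows(
    role_ev("gc", "susC"), role_ev("gd", "susD"),
    role_ev("gt", "tbdt"), role_ev("gs", "sulfatase"),
    role_ev("gp", "peptidase"))
  roles <- detect_sus_components(ev)
  expect_equal(roles$role[roles$gene_id == "gc"], "susC")
  expect_equal(roles$role[roles$gene_id == "gd"], "susD")
  expect_equal(roles$role[roles$gene_id == "gt"], "tbdt_non_susC")
  expect_equal(roles$label[roles$gene_id == "gs"], "S1_15")  # subfamily kept
  expect_equal(roles$role[roles$gene_id == "gp"], "peptidase")

  # a susC-model hit suppresses the generic TBDT role on the same gene
  both <- dplyr::bind_rows(role_ev("g", "susC"), role_ev("g", "tbdt"))
  r <- detect_sus_components(both)
  expect_equal(r$role[r$gene_id == "g"], "susC")

  # a MEROPS hit below E<=1e-4 (score 4) is ignored
  weak <- role_ev("gw", "peptidase", score = 2)
  expect_equal(nrow(detect_sus_components(weak)), 0L)
})

test_that("susC and susD are mutually exclusive on one gene", {
  ev <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g", source = "tigrfam", label = "TIGR04056",
                   score = 500),
    tibble::tibble(gene_id = "g", source = "pfam", label = "PF12741",
                   score = 30))
  expect_message(r <- detect_sus_components(ev), "conflict")
  expect_equal(r$role[r$gene_id == "g"], "susC")  # higher relative score
})

test_that("consensus assignments agree with a brute-force recount under planted decoys", {
  cfg <- annotation_config()
  for (seed in 1:6) {
    set.seed(seed)
    ev <- list()
    for (i in 1:25) {
      g <- sprintf("g%02d", i)
      fam <- sample(c("GH16", "GH3", "PL7", "CBM6", "GH92"), 1)
      if (i %% 3 == 0) {           # planted 2-of-3 consensus
        ev[[length(ev) + 1L]] <- caz_ev(g, fam,
                                        sample(c("pfam", "dbcan", "cazy_blast"),
                                               sample(2:3, 1)))
      } else {                     # single-source decoy, must not annotate
        ev[[length(ev) + 1L]] <- caz_ev(g, fam,
                                        sample(c("pfam", "dbcan", "cazy_blast"), 1))
      }
      if (runif(1) < 0.3) {        # sub-threshold extra row
        ev[[length(ev) + 1L]] <- caz_ev(g, fam, "cazy_blast", score = 1)
      }
    }
    ev <- dplyr::bind_rows(ev)
    got <- assign_cazyme_families(ev, cfg)
    want <- brute_force_families(ev, cfg$thresholds)
    got_split <- split(got$family, got$gene_id)
    expect_equal(lapply(got_split, sort), want[names(got_split)])
    expect_setequal(names(got_split), names(want))
  }
})

test_that("adding evidence rows never removes an assigned family", {
  set.seed(42)
  base <- dplyr::bind_rows(caz_ev("g1", "GH16"), caz_ev("g2", "GH3", "pfam"))
  fam0 <- assign_cazyme_families(base)
  extra <- dplyr::bind_rows(base, caz_ev("g2", "GH3", "dbcan"),
                            caz_ev("g1", "PL7", "cazy_blast"))
  fam1 <- assign_cazyme_families(extra)
  for (k in seq_len(nrow(fam0))) {
    expect_true(any(fam1$gene_id == fam0$gene_id[k] &
                      fam1$family == fam0$family[k]))
  }
  expect_true("g2" %in% fam1$gene_id)  # new consensus appears
})

test_that("genome summaries compute densities and ratios with degenerate guards", {
  mk_assign <- function(n_caz, n_pept, fam = "GH16") {
    fams <- if (n_caz > 0) {
      tibble::tibble(gene_id = sprintf("c%d", seq_len(n_caz)), family = fam,
                     family_raw = fam, sources = "dbcan,pfam", n_sources = 2L)
    } else {
      tibble::tibble(gene_id = character(), family = character(),
                     family_raw = character(), sources = character(),
                     n_sources = integer())
    }
    roles <- if (n_pept > 0) {
      tibble::tibble(gene_id = sprintf("p%d", seq_len(n_pept)),
                     role = "peptidase", label = "M14")
    } else {
      tibble::tibble(gene_id = character(), role = character(),
                     label = character())
    }
    structure(list(families = fams, roles = roles,
                   config = annotation_config()),
              class = "feature_assignments")
  }
  g <- toy_genome(c("a", "b"))
  g$size_bp <- 2e6

  s <- summarize_genome(g, mk_assign(110, 0))
  expect_equal(s$degradative_cazymes_per_mbp, 55)

  s <- summarize_genome(g, mk_assign(10, 18))
  expect_equal(s$peptidase_cazyme_ratio, 1.8)

  s <- summarize_genome(g, mk_assign(0, 5))
  expect_true(is.na(s$peptidase_cazyme_ratio))  # missing, not infinite

  # CBM-only genes are not degradative
  a <- mk_assign(3, 0, fam = "CBM6")
  expect_equal(summarize_genome(g, a)$n_degradative_cazymes, 0L)
})
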