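test_that("technical duplicates average arithmetically with absent replicates tolerated", {
  df <- counts_from_wide(
    data.frame(protein_id = "p1", length = 300L, s1 = 0), replicates = 2L)
  df$spectral_count <- c(4, 6)
  av <- average_technical_duplicates(df)
  expect_equal(av$spectral_count, 5)
  expect_equal(av$n_replicates, 2L)

  single <- df[1, ]
  single$spectral_count <- 7
  expect_equal(average_technical_duplicates(single)$spectral_count, 7)

  zeros <- df
  zeros$spectral_count <- c(0, 0)
  av0 <- average_technical_duplicates(zeros)
  expect_equal(av0$spectral_count, 0)  # retained for normalization
})

test_that("%NSAF matches its definitional worked examples", {
  # 30 of 3000 length-adjusted spectra at equal length -> exactly 1 %NSAF
  tab <- tibble::tibble(protein_id = c("A", "B"), sample_id = "s1",
                        spectral_count = c(30, 2970),
                        protein_length_aa = c(300L, 300L))
  ns <- compute_pct_nsaf(tab)
  expect_equal(ns$pct_nsaf[ns$protein_id == "A"], 1.0)

  one <- compute_pct_nsaf(tibble::tibble(
    protein_id = "A", sample_id = "s1", spectral_count = 5,
    protein_length_aa = 100L))
  expect_equal(one$pct_nsaf, 100)

  two <- compute_pct_nsaf(tibble::tibble(
    protein_id = c("A", "B"), sample_id = "s1", spectral_count = c(10, 10),
    protein_length_aa = c(100L, 400L)))
  expect_equal(sort(two$pct_nsaf), c(20, 80))

  allzero <- tibble::tibble(protein_id = c("A", "B"), sample_id = "s1",
                            spectral_count = 0, protein_length_aa = 100L)
  expect_error(compute_pct_nsaf(allzero), "all-zero")
})

test_that("%NSAF conserves 100 per sample and is invariant to count rescaling", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    tab <- tibble::tibble(
      protein_id = sprintf("p%02d", seq_len(n)),
      sample_id = sample(c("s1", "s2"), n, replace = TRUE),
      spectral_count = rpois(n, 20) + 1,
      protein_length_aa = sample(100:500, n, replace = TRUE))
    ns <- compute_pct_nsaf(tab)
    sums <- tapply(ns$pct_nsaf, ns$sample_id, sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)

    scaled <- tab
    scaled$spectral_count <- tab$spectral_count * 7.3
    expect_equal(compute_pct_nsaf(scaled)$pct_nsaf, ns$pct_nsaf,
                 tolerance = 1e-12)
  }
})

test_that("placement inherits substrates above the 40% threshold with tie handling", {
  refs <- c(r_lam = "ACDEFGHIKLMNPQRSTVWY", r_alg = "YWVTSRQPNMLKIHGFEDCA")
  subs <- c(r_lam = "laminarin", r_alg = "alginate")
  pl <- place_expressed(c(q = "ACDEFGHIKLMNPQRSTVWY"), refs, subs)
  expect_equal(pl$placement_identity, 100)
  expect_equal(pl$inherited_substrate, "laminarin")
  expect_equal(pl$status, "placed")

  # threshold boundary via an injected identity function: 39.9 fails, 40 passes
  fake_id <- function(v) function(a, b) v
  pl_low <- place_expressed(c(q = "AAAA"), refs[1], subs,
                            identity_fun = fake_id(39.9))
  expect_equal(pl_low$status, "unclassified")
  expect_true(is.na(pl_low$inherited_substrate))
  pl_at <- place_expressed(c(q = "AAAA"), refs[1], subs,
                           identity_fun = fake_id(40))
  expect_equal(pl_at$status, "placed")

  # ties across substrates are ambiguous; ties within one substrate inherit
  pl_tie <- place_expressed(c(q = "AAAA"), refs, subs,
                            identity_fun = fake_id(55))
  expect_equal(pl_tie$status, "ambiguous")
  subs_same <- c(r_lam = "laminarin", r_alg = "laminarin")
  pl_same <- place_expressed(c(q = "AAAA"), refs, subs_same,
                             identity_fun = fake_id(55))
  expect_equal(pl_same$inherited_substrate, "laminarin")

  expect_error(place_expressed(c(q = "AAAA"), character(), subs),
               "empty reference")
})

test_that("profiles apply the 0.05 %NSAF retention filter and sum per substrate", {
  md <- tibble::tibble(sample_id = c("s1", "s2"),
                       date = as.Date(c("2010-05-04", "2010-05-11")),
                       chlorophyll_a = c(6, 3), bloom_phase = c("mid", "late"))
  expr <- tibble::tibble(
    protein_id = c("a", "a", "b", "b", "c", "c", "d", "d"),
    sample_id = rep(c("s1", "s2"), 4),
    pct_nsaf = c(0.13, 0.01,   # a: retained, peak 0.13
                 0.04, 0.02,   # b: peaks at 0.04 -> dropped everywhere
                 0.06, 0.01,   # c,d: same substrate, s1 sums to 0.13
                 0.07, 0.0),
    protein_class = c("susC_like", "susC_like", "susC_like", "susC_like",
                      "susD_like", "susD_like", "susD_like", "susD_like"),
    inherited_substrate = c("laminarin", "laminarin", "xylan", "xylan",
                            "beta_mannan", "beta_mannan", "beta_mannan",
                            "beta_mannan"))
  res <- build_substrate_profile(expr, md, min_pct_nsaf = 0.05)
  prof <- res$profile
  expect_equal(res$dropped_proteins, "b")
  expect_false("xylan" %in% prof$substrate)
  expect_equal(prof$pct_nsaf[prof$substrate == "laminarin" &
                               prof$sample_id == "s1"], 0.13)
  expect_equal(prof$pct_nsaf[prof$substrate == "beta_mannan" &
                               prof$sample_id == "s1"], 0.13)
  expect_equal(unique(prof$bloom_phase[prof$sample_id == "s1"]), "mid")
  # susC and susD are never pooled
  expect_false(any(duplicated(
    prof[, c("substrate", "sample_id", "protein_class")])))

  # a protein peaking exactly at the threshold is retained
  at <- expr[expr$protein_id == "b", ]
  at$pct_nsaf <- c(0.05, 0.01)
  res_at <- build_substrate_profile(at, md, min_pct_nsaf = 0.05)
  expect_length(res_at$dropped_proteins, 0L)

  # raising the threshold never adds proteins
  for (thr in c(0.01, 0.05, 0.1, 0.2)) {
    lo <- build_substrate_profile(expr, md, min_pct_nsaf = thr)
    hi <- build_substrate_profile(expr, md, min_pct_nsaf = thr + 0.05)
    expect_true(all(unique(hi$retained$protein_id) %in%
                      unique(lo$retained$protein_id)))
  }
})

test_that("bloom phases follow chlorophyll thresholds and explicit labels win", {
  md <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    date = as.Date("2010-03-01") + 7 * (0:7),
    chlorophyll_a = c(0.5, 1.5, 3, 6, 8, 6, 3, 1),
    bloom_phase = NA_character_)
  ph <- assign_bloom_phase(md, thresholds = c(2, 5))
  expect_equal(ph$bloom_phase, c("pre", "pre", "early", "mid", "mid",
                                 "mid", "late", "late"))

  md$bloom_phase[1] <- "late"  # explicit label overrides
  ph2 <- assign_bloom_phase(md, thresholds = c(2, 5))
  expect_equal(ph2$bloom_phase[1], "late")

  low <- md
  low$bloom_phase <- NA_character_
  low$chlorophyll_a <- seq(0.1, 1.5, length.out = 8)
  expect_true(all(assign_bloom_phase(low, c(2, 5))$bloom_phase == "pre"))

  nochl <- md
  nochl$bloom_phase <- NA_character_
  nochl$chlorophyll_a <- NA_real_
  expect_error(assign_bloom_phase(nochl), "chlorophyll")

  labelled <- md
  labelled$bloom_phase <- rep(c("pre", "mid"), 4)
  expect_equal(assign_bloom_phase(labelled)$bloom_phase,
               labelled$bloom_phase)
})
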