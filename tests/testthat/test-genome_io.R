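test_that("GFF 1-based inclusive coordinates convert to 0-based half-open and round-trip", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  seqs <- list(g1 = rand_aa(99), g2 = rand_aa(50), g3 = rand_aa(70))
  write_toy_gff(gff, data.frame(
    contig = "c1", start1 = c(1L, 1000L, 2000L),
    end1 = c(300L, 1152L, 2212L), strand = c("+", "-", "+"),
    id = c("g1", "g2", "g3")))
  write_toy_faa(faa, seqs)
  g <- read_genome(gff, faa, genome_id = "t")
  expect_s3_class(g$genes, "tbl_df")
  expect_equal(nrow(g$genes), 3L)
  # GFF CDS at 1..300 -> internal [0, 300)
  expect_equal(g$genes$start[g$genes$gene_id == "g1"], 0L)
  expect_equal(g$genes$end[g$genes$gene_id == "g1"], 300L)
  expect_equal(g$genes$gene_id, c("g1", "g2", "g3"))  # coordinate order
  expect_equal(g$genes$protein_seq, unname(unlist(seqs)))

  # write back out and re-read: identical gene records (bijection)
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  faa2 <- withr::local_tempfile(fileext = ".faa")
  write_genome(g, gff2, faa2)
  g2 <- read_genome(gff2, faa2, genome_id = "t", size_bp = g$size_bp)
  expect_equal(as.data.frame(g2$genes), as.data.frame(g$genes))
})

test_that("genes missing a protein sequence are dropped with a warning and counted", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  write_toy_gff(gff, data.frame(
    contig = "c1", start1 = c(1L, 400L, 900L), end1 = c(303L, 702L, 1202L),
    strand = "+", id = c("g1", "g2", "g3")))
  write_toy_faa(faa, list(g1 = rand_aa(100), g3 = rand_aa(100)))
  expect_warning(g <- read_genome(gff, faa), "dropped")
  expect_equal(nrow(g$genes), 2L)
  expect_equal(attr(g, "n_dropped"), 1L)
  expect_setequal(g$genes$gene_id, c("g1", "g3"))
})

test_that("malformed GFF lines and duplicate ids are rejected with informative errors", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c("##gff-version 3",
               "c1\ttoy\tCDS\t1\t300\t.\t+\t0\tID=g1",
               "c1\ttoy\tCDS\t400\t702"), gff)
  write_toy_faa(faa, list(g1 = rand_aa(100)))
  expect_error(read_genome(gff, faa), "malformed GFF line 3")

  write_toy_gff(gff, data.frame(contig = "c1", start1 = c(1L, 400L),
                                end1 = c(303L, 702L), strand = "+",
                                id = c("g1", "g1")))
  expect_error(read_genome(gff, faa), "duplicate gene_id")
})

test_that("evidence reader types rows and enforces the source enum", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsource\tlabel\tscore", "g1\tpfam\tGH16\t55.2"), tsv)
  ev <- read_evidence(tsv)
  expect_equal(as.list(ev[1, ]),
               list(gene_id = "g1", source = "pfam", label = "GH16",
                    score = 55.2))

  writeLines("gene_id\tsource\tlabel\tscore", tsv)
  expect_equal(nrow(read_evidence(tsv)), 0L)

  writeLines(c("gene_id\tsource\tlabel\tscore", "g1\tinterpro\tGH16\t55.2"),
             tsv)
  expect_error(read_evidence(tsv), "interpro")

  writeLines(c("gene_id\tsource\tlabel\tscore", "g1\tpfam\tGH16\thigh"), tsv)
  expect_error(read_evidence(tsv), "non-numeric")
})

test_that("spectral-count and metadata readers validate their contracts", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tsample_id\treplicate_id\tspectral_count\tprotein_length_aa",
               "p1\ts1\tR1\t4\t300", "p1\ts1\tR2\t6\t300"), tsv)
  cnt <- read_spectral_counts(tsv)
  expect_equal(nrow(cnt), 2L)
  writeLines(c("protein_id\tsample_id\treplicate_id\tspectral_count\tprotein_length_aa",
               "p1\ts1\tR1\t4\t300", "p1\ts1\tR1\t6\t300"), tsv)
  expect_error(read_spectral_counts(tsv), "duplicate")

  writeLines(c("sample_id\tdate\tchlorophyll_a",
               "s2\t2010-04-08\t6.1", "s1\t2010-03-30\t1.2"), tsv)
  md <- read_sample_metadata(tsv)
  expect_equal(md$sample_id, c("s1", "s2"))  # chronological
  writeLines(c("sample_id\tdate", "s1\tApril 8"), tsv)
  expect_error(read_sample_metadata(tsv), "date")
})

test_that("outputs are deterministic byte for byte and trees round-trip", {
  layout <- c(x = "", a = "susC", b = "susD", c = "GH16", d = "GH3",
              e = "GH16", y = "", f = "", q = "", r = "", s = "",
              g = "GH13", h = "GH65", i = "GH31")
  puls <- detect_from_layout(layout, gap_tolerance = 2L)
  expect_equal(nrow(puls), 2L)
  preds <- classify_puls(puls)
  tree <- ape::rtree(4)
  tree$tip.label <- paste0("p", 1:4)
  res <- list(puls = puls, predictions = preds, trees = list(susC = tree))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_outputs(res, d1)
  m2 <- write_outputs(res, d2)
  expect_equal(m1$rows[m1$file == "puls.tsv"], 2L)
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  back <- ape::read.tree(file.path(d1, "tree_susC.nwk"))
  expect_setequal(back$tip.label, tree$tip.label)
})
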