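# In-code fixtures: toy genomes, evidence tables and count tables.

rand_aa <- function(n, seed = NULL) {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(letters20, n, replace = TRUE), collapse = "")
}

# genome whose genes are laid out left to right on one contig;
# protein sequences are arbitrary unless supplied
toy_genome <- function(gene_ids, genome_id = "toy", contig = "c1",
                       seqs = NULL) {
  n <- length(gene_ids)
  if (is.null(seqs)) seqs <- vapply(seq_len(n), function(i) rand_aa(60),
                                    character(1))
  starts <- seq(0L, by = 1000L, length.out = n)
  genes <- tibble::tibble(
    gene_id = gene_ids, contig_id = contig, start = starts,
    end = starts + 3L * nchar(seqs) + 3L, strand = "+",
    protein_seq = seqs, length_aa = nchar(seqs))
  new_genome(genome_id, genes, max(genes$end) + 100L)
}

# consensus evidence (2 sources) for a CAZyme family on a gene
caz_ev <- function(gene, fam, sources = c("pfam", "dbcan"), score = 60) {
  tibble::tibble(gene_id = gene, source = sources, label = fam,
                 score = score)
}

role_ev <- function(gene, role,
                    label = switch(role, susC = "TIGR04056",
                                   susD = "PF12741", tbdt = "PF00593",
                                   sulfatase = "S1_15", peptidase = "M14"),
                    score = switch(role, susC = 400, susD = 80, tbdt = 80,
                                   sulfatase = 60, peptidase = 10)) {
  src <- switch(role, susC = "tigrfam", susD = "pfam", tbdt = "pfam",
                sulfatase = "sulfatlas", peptidase = "merops")
  tibble::tibble(gene_id = gene, source = src, label = label, score = score)
}

# evidence table for a gene layout given as a named layout vector:
# names are gene ids, values are slot strings ("", "susC", "GH16", ...)
layout_evidence <- function(layout) {
  ev <- list()
  for (g in names(layout)) {
    slot <- layout[[g]]
    if (slot == "" || slot == "susE") next
    if (slot %in% c("susC", "susD", "tbdt", "sulfatase", "peptidase")) {
      ev[[length(ev) + 1L]] <- role_ev(g, slot)
    } else {
      for (fam in strsplit(slot, "+", fixed = TRUE)[[1]]) {
        ev[[length(ev) + 1L]] <- caz_ev(g, fam)
      }
    }
  }
  if (length(ev) == 0) {
    return(tibble::tibble(gene_id = character(), source = character(),
                          label = character(), score = numeric()))
  }
  dplyr::bind_rows(ev)
}

# build genome + assignments from a layout vector, then detect PULs
detect_from_layout <- function(layout, gap_tolerance = 3L, min_cazymes = 2L,
                               genome_id = "toy") {
  g <- toy_genome(names(layout), genome_id = genome_id)
  a <- assign_features(layout_evidence(layout))
  detect_puls(g, a, gap_tolerance = gap_tolerance, min_cazymes = min_cazymes)
}

# minimal pul-like list for classify_pul
fake_pul <- function(multiset, n_sulfatases = 0L, completeness = "complete",
                     has_susE = FALSE, pul_id = "p1") {
  list(pul_id = pul_id, family_multiset = multiset,
       n_sulfatases = n_sulfatases, completeness = completeness,
       has_susE = has_susE)
}

# spectral-count tibble from a matrix-like spec:
# data.frame(protein_id, length, counts per sample...)
counts_from_wide <- function(df, replicates = 1L) {
  samples <- setdiff(names(df), c("protein_id", "length"))
  rows <- list()
  for (i in seq_len(nrow(df))) {
    for (s in samples) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          protein_id = df$protein_id[i], sample_id = s,
          replicate_id = paste0("R", r),
          spectral_count = df[[s]][i], protein_length_aa = df$length[i])
      }
    }
  }
  dplyr::bind_rows(rows)
}

write_toy_gff <- function(path, rows) {
  # rows: data.frame contig, start1, end1, strand, id  (1-based inclusive)
  lines <- c("##gff-version 3",
             sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
                     rows$contig, rows$start1, rows$end1, rows$strand,
                     rows$id, rows$id))
  writeLines(lines, path)
  path
}

write_toy_faa <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}
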