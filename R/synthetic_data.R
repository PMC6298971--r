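#' Seeded synthetic genomes and metaproteomes
#'
#' Generates inputs with the statistical structure the pipeline assumes:
#' genomes carrying planted PULs built from architecture templates (with
#' 2-of-3 consensus evidence for planted families and single-source decoy
#' evidence that must not be annotated), substrate-specific SusC/D protein
#' families with controlled within- and between-family divergence, and
#' metaproteome spectral-count tables with substrate-specific temporal
#' peaks across a chlorophyll-defined bloom. Every output draws from its
#' own pseudo-random stream derived from the master seed, so identical
#' configurations give byte-identical outputs.
#'
#' @name synthetic_data
NULL

# run code under a derived seed without disturbing the caller's RNG state
with_stream_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Defaults define the synthetic study conditions: a handful of genomes
#' each carrying several planted PULs (the surveyed isolates averaged
#' 7.5 PULs per genome), SusC/D families diverged ~0.2 per site within a
#' substrate and ~0.6 between substrates, and a 14-sample metaproteome
#' with two technical replicates per sample spanning one bloom.
#'
#' @param seed master integer seed; all streams derive from it.
#' @param n_genomes number of genomes.
#' @param puls_per_genome planted PULs per genome (templates sampled
#'   uniformly unless `substrate_mix` is given).
#' @param substrate_mix optional named integer vector: template name ->
#'   count per genome.
#' @param min_decoy_run minimum decoy genes between planted PULs; must
#'   exceed the detection gap tolerance for planted loci to stay separate.
#' @param mean_extra_decoys Poisson mean of additional decoys per run.
#' @param evidence_noise probability a decoy gene receives one spurious
#'   single-source CAZyme evidence row (never enough for consensus).
#' @param peptidase_rate probability a decoy gene carries MEROPS evidence.
#' @param within_substrate_p per-site substitution probability inside one
#'   SusC/D substrate family.
#' @param between_substrate_p per-site substitution probability between
#'   substrate-family ancestors.
#' @param suscd_length SusC/D ancestor length in amino acids (desk-scale).
#' @param n_samples,replicates metaproteome samples and technical
#'   replicates.
#' @param n_background background proteins per metaproteome sample.
#' @param baseline_count,peak_height,peak_width planted homolog mean
#'   spectral counts: baseline plus a Gaussian bump of the given height
#'   and width (in samples) at the substrate's peak sample.
#' @param query_divergence_p divergence of expressed homologs from their
#'   reference family member.
#' @param count_noise `"poisson"` (replicate counts drawn around the
#'   mean) or `"none"` (counts equal configured means exactly).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_genomes = 6L, puls_per_genome = 7L,
                             substrate_mix = NULL, min_decoy_run = 4L,
                             mean_extra_decoys = 2, evidence_noise = 0.1,
                             peptidase_rate = 0.1,
                             within_substrate_p = 0.2,
                             between_substrate_p = 0.6,
                             suscd_length = 300L,
                             n_samples = 14L, replicates = 2L,
                             n_background = 150L,
                             baseline_count = 0.5, peak_height = 30,
                             peak_width = 1,
                             query_divergence_p = 0.1,
                             count_noise = c("poisson", "none")) {
  count_noise <- match.arg(count_noise)
  probs <- c(evidence_noise, peptidase_rate, within_substrate_p,
             between_substrate_p, query_divergence_p)
  stopifnot(all(probs >= 0 & probs <= 1), n_genomes >= 0L,
            min_decoy_run >= 1L, n_samples >= 1L, replicates >= 1L)
  structure(list(seed = as.integer(seed), n_genomes = n_genomes,
                 puls_per_genome = puls_per_genome,
                 substrate_mix = substrate_mix,
                 min_decoy_run = min_decoy_run,
                 mean_extra_decoys = mean_extra_decoys,
                 evidence_noise = evidence_noise,
                 peptidase_rate = peptidase_rate,
                 within_substrate_p = within_substrate_p,
                 between_substrate_p = between_substrate_p,
                 suscd_length = as.integer(suscd_length),
                 n_samples = as.integer(n_samples),
                 replicates = as.integer(replicates),
                 n_background = as.integer(n_background),
                 baseline_count = baseline_count,
                 peak_height = peak_height, peak_width = peak_width,
                 query_divergence_p = query_divergence_p,
                 count_noise = count_noise),
            class = "generator_config")
}

#' PUL architecture templates
#'
#' Ordered gene slots per template; slot vocabulary: `susC`, `susD`,
#' `susE` (plain gene, no evidence), `tbdt` (generic TBDT), `sulfatase`,
#' a CAZy family label, or two family labels joined by `+` for one gene
#' carrying both. Templates mirror the recurrent architectures: e.g.
#' laminarin A is a GH3 framed by two GH16 genes behind a susCD tandem.
#' Three templates deliberately lack a complete tandem to exercise the
#' incomplete-PUL subtypes.
#'
#' @return Named list of templates: `slots`, `substrate`, `variant`,
#'   `completeness` (expected class).
#' @export
pul_templates <- function() {
  t <- function(slots, substrate, variant = NA_character_,
                completeness = "complete") {
    list(slots = slots, substrate = substrate, variant = variant,
         completeness = completeness)
  }
  list(
    laminarin_A = t(c("susC", "susD", "GH16", "GH3", "GH16"),
                    "laminarin", "A"),
    laminarin_B = t(c("susC", "susD", "GH30", "GH17", "GH17", "GH16"),
                    "laminarin", "B"),
    laminarin_C = t(c("susC", "susD", "GH16", "GH30", "GH5+CBM6"),
                    "laminarin", "C"),
    laminarin_D = t(c("susC", "susD", "GH16", "GH30", "GH5"),
                    "laminarin", "D"),
    alpha14_glucan_branched = t(c("susC", "susD", "susE", "GH13", "GH65",
                                  "GH31"), "alpha14_glucan", "branched"),
    alpha14_glucan_simple = t(c("susC", "susD", "GH13", "GH65"),
                              "alpha14_glucan", "simple"),
    alginate = t(c("susC", "susD", "PL6", "PL7", "PL17"), "alginate"),
    alpha_mannan_sulfated = t(c("susC", "susD", "GH92", "GH92", "GH92",
                                "sulfatase", "sulfatase"),
                              "alpha_mannan", "sulfated"),
    alpha_mannan_plain = t(c("susC", "susD", "GH76", "GH125", "GH38"),
                           "alpha_mannan", "plain"),
    beta_mannan = t(c("susC", "susD", "GH130", "GH26"), "beta_mannan"),
    fcsp = t(c("susC", "susD", "GH29", "GH95", "sulfatase"), "fcsp"),
    xylan_sulfated = t(c("susC", "susD", "GH10", "GH43", "sulfatase"),
                       "xylan", "sulfated"),
    xylan_glucurono = t(c("susC", "susD", "GH10", "GH115"), "xylan",
                        "glucurono"),
    xylan_arabino = t(c("susC", "susD", "GH10", "GH43", "GH51"), "xylan",
                      "arabino"),
    alginate_no_susCD = t(c("PL6", "PL7", "PL17"), "alginate",
                          completeness = "no_susCD"),
    xylan_no_susD = t(c("susC", "GH10", "GH43"), "xylan",
                      completeness = "no_susD"),
    beta_mannan_tbdt = t(c("tbdt", "GH130", "GH26"), "beta_mannan",
                         completeness = "tbdt_only")
  )
}

random_protein <- function(length_aa) {
  paste(sample(AA20, length_aa, replace = TRUE), collapse = "")
}

# mutate each site i.i.d. with probability p, uniformly over the 19 others
mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < p
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a mutated protein family
#'
#' Draws a random ancestor and mutates each member i.i.d. per site with
#' probability `p_subst` (uniform over the 19 alternative residues).
#' Expected pairwise identity between members is approximately
#' `100 x ((1 - p)^2 + p^2/19 + 2 p (1-p)/19)` (two members match when
#' neither site mutated, or both mutated to the same residue).
#'
#' @param ancestor_length ancestor length in amino acids.
#' @param n number of family members.
#' @param p_subst per-site substitution probability.
#' @param seed integer seed for this family's stream.
#' @return Named character vector of `n` sequences (`member_01`, ...),
#'   with the ancestor attached as attribute `ancestor`.
#' @export
generate_protein_family <- function(ancestor_length, n, p_subst, seed) {
  with_stream_seed(seed, {
    anc <- random_protein(ancestor_length)
    members <- vapply(seq_len(n), function(i) mutate_protein(anc, p_subst),
                      character(1L))
    names(members) <- sprintf("member_%02d", seq_len(n))
    attr(members, "ancestor") <- anc
    members
  })
}

# Substrate-family ancestors for SusC and SusD, shared across genomes:
# one class root each, family ancestors diverged by between_substrate_p.
suscd_family_ancestors <- function(config) {
  substrates <- unique(vapply(pul_templates(), function(t) t$substrate,
                              character(1L)))
  with_stream_seed(derive_seed(config$seed, "suscd_roots"), {
    out <- list()
    for (cls in c("susC", "susD")) {
      root <- random_protein(config$suscd_length)
      anc <- vapply(substrates, function(s) {
        mutate_protein(root, config$between_substrate_p)
      }, character(1L))
      out[[cls]] <- anc
    }
    out
  })
}

#' Generate labelled SusC/D sequence families
#'
#' Draws one class root, diverges a family ancestor per substrate by
#' `between_substrate_p`, and emits `n_per_family` members per substrate
#' at `within_substrate_p` divergence — the sequence structure behind the
#' substrate-specific clusters in the reference trees.
#'
#' @param config a [generator_config()].
#' @param substrates substrate labels (one family each).
#' @param n_per_family members per family.
#' @param protein_class `"susC"` or `"susD"` (separate streams and roots).
#' @return Tibble: `protein_id`, `substrate`, `seq`, with the family
#'   ancestors attached as attribute `ancestors`.
#' @export
generate_suscd_families <- function(config, substrates, n_per_family = 4L,
                                    protein_class = c("susC", "susD")) {
  protein_class <- match.arg(protein_class)
  with_stream_seed(
    derive_seed(config$seed, paste0("families_", protein_class)), {
      root <- random_protein(config$suscd_length)
      anc <- vapply(substrates, function(s) {
        mutate_protein(root, config$between_substrate_p)
      }, character(1L))
      rows <- lapply(substrates, function(s) {
        tibble::tibble(
          protein_id = sprintf("%s_%s_%02d", protein_class, s,
                               seq_len(n_per_family)),
          substrate = s,
          seq = vapply(seq_len(n_per_family), function(i) {
            mutate_protein(anc[[s]], config$within_substrate_p)
          }, character(1L)))
      })
      out <- dplyr::bind_rows(rows)
      attr(out, "ancestors") <- anc
      out
    })
}

# scores comfortably above the acceptance thresholds
.sim_score <- function(source, n = 1L) {
  switch(source,
         pfam = stats::runif(n, 40, 150),
         dbcan = stats::runif(n, 40, 150),
         tigrfam = stats::runif(n, 300, 600),
         sulfatlas = stats::runif(n, 40, 120),
         cazy_blast = stats::runif(n, 8, 80),
         merops = stats::runif(n, 8, 60))
}

#' Generate one synthetic genome with planted PULs
#'
#' Plants templated PULs separated by runs of unannotated decoy genes,
#' emits 2-of-3 consensus evidence for every planted CAZyme family (plus
#' role evidence for susC/susD/TBDT/sulfatase slots), optional
#' single-source decoy evidence at rate `evidence_noise`, and a truth
#' table recording each planted locus. SusC/D protein sequences are drawn
#' from the shared substrate families so downstream tree and placement
#' tests are meaningful; all other protein sequences are random.
#'
#' @param config a [generator_config()].
#' @param genome_index which genome to generate (1-based; each genome has
#'   its own stream).
#' @param ancestors optional precomputed [suscd_family_ancestors] result
#'   (computed from `config` when NULL).
#' @return List: `genome` (a `pul_genome`), `evidence` (tibble),
#'   `truth` (tibble: `pul_ordinal`, `template`, `substrate`, `variant`,
#'   `completeness`, `gene_ids` comma-joined).
#' @export
generate_genome <- function(config, genome_index = 1L, ancestors = NULL) {
  templates <- pul_templates()
  if (is.null(ancestors)) ancestors <- suscd_family_ancestors(config)
  genome_id <- sprintf("synth%02d", genome_index)
  with_stream_seed(derive_seed(config$seed, paste0("genome", genome_index)), {
    chosen <- if (!is.null(config$substrate_mix)) {
      rep(names(config$substrate_mix), config$substrate_mix)
    } else {
      sample(names(templates), config$puls_per_genome, replace = TRUE)
    }
    genes <- list()
    evidence <- list()
    truth <- list()
    pos <- 0L
    gi <- 0L
    add_gene <- function(len_aa, seq = NULL) {
      gi <<- gi + 1L
      id <- sprintf("%s_g%04d", genome_id, gi)
      if (is.null(seq)) seq <- random_protein(len_aa)
      nt <- 3L * nchar(seq) + 3L
      start <- pos + sample(50:200, 1L)
      genes[[length(genes) + 1L]] <<- tibble::tibble(
        gene_id = id, contig_id = "contig1", start = start,
        end = start + nt, strand = sample(c("+", "-"), 1L),
        protein_seq = seq, length_aa = nchar(seq))
      pos <<- start + nt
      id
    }
    add_ev <- function(gene_id, source, label, score) {
      evidence[[length(evidence) + 1L]] <<- tibble::tibble(
        gene_id = gene_id, source = source, label = label, score = score)
    }
    add_decoys <- function(n) {
      for (k in seq_len(n)) {
        id <- add_gene(sample(150:400, 1L))
        if (stats::runif(1L) < config$evidence_noise) {
          src <- sample(c("pfam", "dbcan", "cazy_blast"), 1L)
          add_ev(id, src, paste0("GH", sample(1:150, 1L)), .sim_score(src))
        }
        if (stats::runif(1L) < config$peptidase_rate) {
          add_ev(id, "merops", paste0("M", sample(1:80, 1L)),
                 .sim_score("merops"))
        }
      }
    }
    decoy_run <- function() {
      config$min_decoy_run + stats::rpois(1L, config$mean_extra_decoys)
    }
    add_decoys(decoy_run())
    for (tn in chosen) {
      tpl <- templates[[tn]]
      ids <- character(length(tpl$slots))
      for (s in seq_along(tpl$slots)) {
        slot <- tpl$slots[s]
        if (slot == "susC" || slot == "susD") {
          seq <- mutate_protein(ancestors[[slot]][[tpl$substrate]],
                                config$within_substrate_p)
          id <- add_gene(nchar(seq), seq)
          if (slot == "susC") {
            add_ev(id, "tigrfam", "TIGR04056", .sim_score("tigrfam"))
          } else {
            add_ev(id, "pfam", sample(c("PF12741", "PF12771", "PF14322"), 1L),
                   .sim_score("pfam"))
          }
        } else if (slot == "susE") {
          id <- add_gene(sample(200:350, 1L))  # no evidence: positional call
        } else if (slot == "tbdt") {
          id <- add_gene(sample(600:900, 1L))
          add_ev(id, "pfam", "PF00593", .sim_score("pfam"))
        } else if (slot == "sulfatase") {
          id <- add_gene(sample(300:500, 1L))
          add_ev(id, "sulfatlas", sample(c("S1_15", "S1_16", "S1_7", "S1_4"), 1L),
                 .sim_score("sulfatlas"))
        } else {
          id <- add_gene(sample(250:450, 1L))
          for (fam in strsplit(slot, "+", fixed = TRUE)[[1]]) {
            srcs <- sample(c("pfam", "dbcan", "cazy_blast"), sample(2:3, 1L))
            for (src in srcs) add_ev(id, src, fam, .sim_score(src))
          }
        }
        ids[s] <- id
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        pul_ordinal = length(truth) + 1L, template = tn,
        substrate = tpl$substrate, variant = tpl$variant,
        completeness = tpl$completeness,
        gene_ids = paste(ids, collapse = ","))
      add_decoys(decoy_run())
    }
    genes <- dplyr::bind_rows(genes)
    evidence <- if (length(evidence) > 0L) dplyr::bind_rows(evidence)
                else tibble::tibble(gene_id = character(), source = character(),
                                    label = character(), score = numeric())
    truth <- if (length(truth) > 0L) dplyr::bind_rows(truth)
             else tibble::tibble(pul_ordinal = integer(), template = character(),
                                 substrate = character(), variant = character(),
                                 completeness = character(), gene_ids = character())
    list(genome = new_genome(genome_id, genes, pos + 500L),
         evidence = evidence, truth = truth)
  })
}

#' Generate the full synthetic genome compendium
#'
#' @param config a [generator_config()].
#' @return List of per-genome results (see [generate_genome()]), plus the
#'   shared `ancestors`.
#' @export
generate_genomes <- function(config) {
  ancestors <- suscd_family_ancestors(config)
  res <- lapply(seq_len(config$n_genomes), function(i) {
    generate_genome(config, i, ancestors)
  })
  names(res) <- vapply(res, function(r) r$genome$genome_id, character(1L))
  list(genomes = res, ancestors = ancestors)
}

#' Generate a synthetic metaproteome
#'
#' Emits spectral-count tables (with technical replicates), expressed
#' query sequences and sample metadata. Expressed SusC/D homologs are
#' drawn from the reference families at `query_divergence_p` divergence;
#' each profiled substrate gets a Gaussian-shaped temporal peak at its
#' assigned sample over a small baseline. Background proteins have
#' time-constant means. Chlorophyll a rises and falls across the series.
#'
#' @param config a [generator_config()].
#' @param reference tibble with columns `protein_id`, `protein_class`
#'   (`susC_like`/`susD_like`), `substrate`, `seq` — typically the
#'   labelled SusC/D proteins of the synthetic PULs.
#' @param n_substrates number of substrates to plant peaks for (default
#'   up to 4, taken in order of appearance in `reference`).
#' @return List: `counts` (spectral-count tibble), `queries` (tibble:
#'   `protein_id`, `protein_class`, `seq`), `metadata`, `truth` (tibble:
#'   `protein_id`, `substrate`, `protein_class`, `peak_sample`).
#' @export
generate_metaproteome <- function(config, reference, n_substrates = 4L) {
  stopifnot(nrow(reference) > 0L)
  subs <- unique(reference$substrate)
  subs <- subs[seq_len(min(n_substrates, length(subs)))]
  n_s <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  with_stream_seed(derive_seed(config$seed, "metaproteome"), {
    peak_at <- if (length(subs) == 1L) round(n_s / 2)
               else round(seq(3, max(3, n_s - 2), length.out = length(subs)))
    reps <- config$replicates
    draw <- function(mu) {
      if (config$count_noise == "poisson") stats::rpois(length(mu), mu)
      else mu
    }
    expand_counts <- function(pid, len_aa, mu_per_sample) {
      mu <- rep(mu_per_sample, each = reps)
      tibble::tibble(
        protein_id = pid,
        sample_id = rep(sample_ids, each = reps),
        replicate_id = rep(sprintf("R%d", seq_len(reps)), times = n_s),
        spectral_count = as.numeric(draw(mu)),
        protein_length_aa = len_aa)
    }
    queries <- list(); truth <- list(); counts <- list()
    for (k in seq_along(subs)) {
      for (cls in c("susC_like", "susD_like")) {
        refs <- reference[reference$substrate == subs[k] &
                            reference$protein_class == cls, , drop = FALSE]
        if (nrow(refs) == 0L) next
        ref <- refs[sample(nrow(refs), 1L), ]
        qid <- sprintf("q_%s_%s", subs[k], sub("_like$", "", cls))
        qseq <- mutate_protein(ref$seq, config$query_divergence_p)
        queries[[length(queries) + 1L]] <- tibble::tibble(
          protein_id = qid, protein_class = cls, seq = qseq)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          protein_id = qid, substrate = subs[k], protein_class = cls,
          peak_sample = sample_ids[peak_at[k]])
        mu_t <- config$baseline_count + config$peak_height *
          exp(-0.5 * ((seq_len(n_s) - peak_at[k]) / config$peak_width)^2)
        counts[[length(counts) + 1L]] <- expand_counts(qid, nchar(qseq), mu_t)
      }
    }
    bg_len <- sample(150:600, config$n_background, replace = TRUE)
    bg_mu <- stats::rgamma(config$n_background, shape = 2, scale = 10) + 5
    for (b in seq_len(config$n_background)) {
      counts[[length(counts) + 1L]] <- expand_counts(
        sprintf("bg_%04d", b), bg_len[b], rep(bg_mu[b], n_s))
    }
    tt <- seq_len(n_s)
    metadata <- tibble::tibble(
      sample_id = sample_ids,
      date = as.Date("2010-03-01") + 7L * (tt - 1L),
      chlorophyll_a = 0.5 + 7.5 * exp(-0.5 * ((tt - stats::median(tt)) / 2.5)^2),
      bloom_phase = NA_character_)
    list(counts = dplyr::bind_rows(counts),
         queries = dplyr::bind_rows(queries),
         metadata = metadata,
         truth = dplyr::bind_rows(truth))
  })
}
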