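#' Declarative substrate rules for PUL classification
#'
#' Maps a PUL's CAZyme family composition, sulfatase content and
#' transporter architecture to a predicted polysaccharide substrate.
#' The built-in table encodes the signatures recurrently observed in
#' marine flavobacterial PULs: four laminarin variants, branched and
#' simple alpha-1,4-glucan, a trehalose-like alpha-1,1-glucan placeholder,
#' alginate, sulfated and non-sulfated alpha-mannan, beta-mannan,
#' fucose-containing sulfated polysaccharides (FCSP) and three beta-xylan
#' subtypes over a GH10/GH43 xylan core.
#'
#' @name substrate_rules
NULL

#' Construct a substrate rule
#'
#' @param name unique rule name (e.g. `"laminarin_A"`).
#' @param substrate substrate label the rule predicts.
#' @param variant optional variant label (e.g. `"A"`).
#' @param required named integer vector: minimum count per family.
#' @param any_of list of clauses `list(families=, min_total=, min_distinct=)`;
#'   each clause requires the summed count over its families to reach
#'   `min_total` and the number of distinct present families to reach
#'   `min_distinct`.
#' @param forbidden families that must be absent from the PUL.
#' @param requires_sulfatase `"yes"`, `"no"` or `"any"`; evaluated on
#'   PUL-internal sulfatase genes only.
#' @param requires_susCDE if TRUE the PUL must have a complete susCD pair
#'   plus a susE-like gene.
#' @param requires_susCD if TRUE the PUL must have a complete susCD pair.
#' @param forbid_susE if TRUE the PUL must have no susE-like gene.
#' @param priority integer; higher priority wins among matching rules
#'   (variant rules above class rules above broad fallbacks).
#' @return A list of class `substrate_rule`.
#' @export
substrate_rule <- function(name, substrate, variant = NA_character_,
                           required = integer(), any_of = list(),
                           forbidden = character(),
                           requires_sulfatase = "any",
                           requires_susCDE = FALSE,
                           requires_susCD = FALSE,
                           forbid_susE = FALSE,
                           priority = 50L) {
  stopifnot(requires_sulfatase %in% c("yes", "no", "any"))
  if (length(required) > 0L && length(forbidden) > 0L &&
      length(intersect(names(required), forbidden)) > 0L) {
    stop("rule '", name, "': required and forbidden families overlap",
         call. = FALSE)
  }
  structure(list(name = name, substrate = substrate, variant = variant,
                 required = required, any_of = any_of, forbidden = forbidden,
                 requires_sulfatase = requires_sulfatase,
                 requires_susCDE = requires_susCDE,
                 requires_susCD = requires_susCD,
                 forbid_susE = forbid_susE,
                 priority = as.integer(priority)),
            class = "substrate_rule")
}

validate_rule_table <- function(rules) {
  names_ <- vapply(rules, function(r) r$name, character(1L))
  if (anyDuplicated(names_)) {
    stop("duplicate rule name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  prio <- vapply(rules, function(r) r$priority, integer(1L))
  if (anyDuplicated(prio)) {
    stop("duplicate rule priority: priorities must be unique", call. = FALSE)
  }
  for (r in rules) {
    fams <- c(names(r$required), r$forbidden,
              unlist(lapply(r$any_of, function(cl) cl$families)))
    bad <- fams[!grepl("^(GH|PL|CE|CBM|AA)[0-9]+$", fams)]
    if (length(bad) > 0L) {
      stop("rule '", r$name, "' uses non-CAZy family label(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  invisible(rules)
}

xylan_core_clause <- function() {
  list(families = c("GH10", "GH43"), min_total = 1L, min_distinct = 1L)
}

#' Built-in substrate rule table
#'
#' Encodes the recurrent PUL signatures: laminarin variants A (a GH3
#' beta-1,3-glucosidase framed by two GH16 beta-1,3(4)-glucanases), B (a
#' GH30 exo-beta-1,6-glucanase plus at least two GH17 beta-1,3-glucan
#' hydrolases), C and D (GH16 + GH30 without GH17 plus a GH5 glucan
#' hydrolase, split here on the presence of a CBM6 binding module);
#' branched alpha-1,4-glucan (susCDE triplet, GH13 plus GH65 and GH31)
#' and its simple variant (GH13 + GH65, no susE); a conservative
#' trehalose-like alpha-1,1-glucan placeholder; alginate (at least two of
#' PL6/PL7/PL17, PL12 optional); sulfated alpha-mannan (multiple GH92 with
#' sulfatases) and plain alpha-mannan (GH76/GH125/GH38, sulfatase-free);
#' beta-mannan (GH130 + GH26); FCSP (GH29/GH95 fucosidases with
#' sulfatases); and xylan subtypes (glucuronoxylan via GH67/GH115,
#' arabinoxylan via GH51, sulfated xylan via PUL sulfatases) over the
#' GH10/GH43 core, with a class-level xylan fallback. The table is
#' user-extensible via [read_rule_table()].
#'
#' @return A validated list of `substrate_rule` objects, ordered by
#'   decreasing priority.
#' @export
default_rule_table <- function() {
  rules <- list(
    substrate_rule("laminarin_A", "laminarin", "A",
                   required = c(GH16 = 2L, GH3 = 1L),
                   forbidden = c("GH17", "GH30"), priority = 120L),
    substrate_rule("laminarin_B", "laminarin", "B",
                   required = c(GH17 = 2L, GH30 = 1L, GH16 = 1L),
                   priority = 119L),
    substrate_rule("laminarin_C", "laminarin", "C",
                   required = c(GH16 = 1L, GH30 = 1L, GH5 = 1L, CBM6 = 1L),
                   forbidden = "GH17", priority = 118L),
    substrate_rule("laminarin_D", "laminarin", "D",
                   required = c(GH16 = 1L, GH30 = 1L, GH5 = 1L),
                   forbidden = c("GH17", "CBM6"), priority = 117L),
    substrate_rule("alpha14_glucan_branched", "alpha14_glucan", "branched",
                   required = c(GH13 = 1L, GH65 = 1L, GH31 = 1L),
                   requires_susCDE = TRUE, priority = 116L),
    substrate_rule("alpha14_glucan_simple", "alpha14_glucan", "simple",
                   required = c(GH13 = 1L, GH65 = 1L),
                   forbid_susE = TRUE, priority = 115L),
    substrate_rule("alginate", "alginate",
                   any_of = list(list(families = c("PL6", "PL7", "PL17"),
                                      min_total = 2L, min_distinct = 2L)),
                   priority = 110L),
    substrate_rule("alpha_mannan_sulfated", "alpha_mannan", "sulfated",
                   required = c(GH92 = 2L),
                   requires_sulfatase = "yes", priority = 109L),
    substrate_rule("alpha_mannan_plain", "alpha_mannan", "plain",
                   any_of = list(list(families = c("GH76", "GH125", "GH38"),
                                      min_total = 1L, min_distinct = 1L)),
                   requires_sulfatase = "no", priority = 108L),
    substrate_rule("beta_mannan", "beta_mannan",
                   required = c(GH130 = 1L, GH26 = 1L), priority = 107L),
    substrate_rule("fcsp", "fcsp",
                   any_of = list(list(families = c("GH29", "GH95"),
                                      min_total = 1L, min_distinct = 1L)),
                   requires_sulfatase = "yes", priority = 106L),
    substrate_rule("xylan_sulfated", "xylan", "sulfated",
                   any_of = list(xylan_core_clause()),
                   requires_sulfatase = "yes", priority = 105L),
    substrate_rule("xylan_glucurono", "xylan", "glucurono",
                   any_of = list(xylan_core_clause(),
                                 list(families = c("GH67", "GH115"),
                                      min_total = 1L, min_distinct = 1L)),
                   priority = 104L),
    substrate_rule("xylan_arabino", "xylan", "arabino",
                   required = c(GH51 = 1L),
                   any_of = list(xylan_core_clause()), priority = 103L),
    substrate_rule("xylan_class", "xylan",
                   any_of = list(xylan_core_clause()), priority = 60L),
    # alpha-1,1-glucan (trehalose-like): placeholder signature; the source
    # material gives no vetted family table for this substrate.
    substrate_rule("alpha11_glucan", "alpha11_glucan",
                   required = c(GH65 = 1L), forbidden = "GH13",
                   priority = 40L)
  )
  validate_rule_table(rules)
}

#' Load a user rule table from YAML
#'
#' Schema per rule: `name`, `substrate`, optional `variant`, `required`
#' (family: min count map), `any_of` (list of `families`/`min_total`/
#' `min_distinct` clauses), `forbidden`, `requires_sulfatase`,
#' `requires_susCDE`, `requires_susCD`, `forbid_susE`, `priority`. When
#' `extend = TRUE` the rules are appended to the built-in table.
#'
#' @param path YAML file path.
#' @param extend append to [default_rule_table()] (default TRUE).
#' @return Validated list of `substrate_rule` objects.
#' @export
read_rule_table <- function(path, extend = TRUE) {
  spec <- yaml::read_yaml(path)
  rules <- lapply(spec, function(r) {
    substrate_rule(
      name = r$name, substrate = r$substrate,
      variant = r$variant %||% NA_character_,
      required = if (is.null(r$required)) integer()
                 else stats::setNames(as.integer(unlist(r$required)),
                                      names(r$required)),
      any_of = lapply(r$any_of %||% list(), function(cl) {
        list(families = as.character(cl$families),
             min_total = as.integer(cl$min_total %||% 1L),
             min_distinct = as.integer(cl$min_distinct %||% 1L))
      }),
      forbidden = as.character(r$forbidden %||% character()),
      requires_sulfatase = r$requires_sulfatase %||% "any",
      requires_susCDE = isTRUE(r$requires_susCDE),
      requires_susCD = isTRUE(r$requires_susCD),
      forbid_susE = isTRUE(r$forbid_susE),
      priority = r$priority)
  })
  if (extend) rules <- c(default_rule_table(), rules)
  validate_rule_table(rules)
}

# Evaluate one rule against a PUL's composition. Returns TRUE/FALSE.
rule_matches <- function(rule, multiset, n_sulfatases, complete, has_susE) {
  count_of <- function(f) if (f %in% names(multiset)) multiset[[f]] else 0L
  if (length(rule$required) > 0L) {
    for (f in names(rule$required)) {
      if (count_of(f) < rule$required[[f]]) return(FALSE)
    }
  }
  for (cl in rule$any_of) {
    counts <- vapply(cl$families, count_of, integer(1L))
    if (sum(counts) < cl$min_total) return(FALSE)
    if (sum(counts > 0L) < cl$min_distinct) return(FALSE)
  }
  for (f in rule$forbidden) if (count_of(f) > 0L) return(FALSE)
  if (rule$requires_sulfatase == "yes" && n_sulfatases < 1L) return(FALSE)
  if (rule$requires_sulfatase == "no" && n_sulfatases > 0L) return(FALSE)
  if (rule$requires_susCDE && !(complete && has_susE)) return(FALSE)
  if (rule$requires_susCD && !complete) return(FALSE)
  if (rule$forbid_susE && has_susE) return(FALSE)
  TRUE
}

#' Classify a single PUL against a rule table
#'
#' Pure function of the PUL's family multiset, PUL-internal sulfatase
#' count and transporter architecture. All rules are evaluated; the
#' highest-priority match (ties broken by table order) is reported and
#' all other matches are listed as ambiguity. With no match the substrate
#' is `"unclassified"`.
#'
#' @param pul one row of a `pul_table`, or a list with elements
#'   `family_multiset` (named integer vector), `n_sulfatases`,
#'   `completeness`, `has_susE` and optionally `pul_id`.
#' @param rules a rule table (default [default_rule_table()]).
#' @return A list of class `substrate_prediction`: `pul_id`, `substrate`,
#'   `variant`, `matched_rule`, `ambiguity` (character vector of other
#'   matching rule names), `n_matches`.
#' @export
classify_pul <- function(pul, rules = default_rule_table()) {
  multiset <- pul$family_multiset
  if (is.list(multiset) && !is.null(multiset[[1]]) && is.numeric(multiset[[1]])) {
    multiset <- multiset[[1]]
  }
  if (is.null(multiset)) multiset <- integer()
  n_sulf <- pul$n_sulfatases %||% 0L
  complete <- identical(pul$completeness, "complete")
  has_susE <- isTRUE(pul$has_susE)
  hits <- Filter(function(r) rule_matches(r, multiset, n_sulf, complete,
                                          has_susE), rules)
  if (length(hits) == 0L) {
    res <- list(pul_id = pul$pul_id %||% NA_character_,
                substrate = "unclassified", variant = NA_character_,
                matched_rule = NA_character_, ambiguity = character(),
                n_matches = 0L)
  } else {
    prio <- vapply(hits, function(r) r$priority, integer(1L))
    top <- hits[[which.max(prio)]]  # ties broken by table order (first max)
    others <- setdiff(vapply(hits, function(r) r$name, character(1L)),
                      top$name)
    res <- list(pul_id = pul$pul_id %||% NA_character_,
                substrate = top$substrate, variant = top$variant,
                matched_rule = top$name, ambiguity = others,
                n_matches = length(hits))
  }
  class(res) <- "substrate_prediction"
  res
}

#' Classify every PUL in a PUL table
#'
#' @param puls a `pul_table` from [detect_puls()].
#' @param rules a rule table.
#' @return Tibble: `pul_id`, `genome_id`, `substrate`, `variant`,
#'   `matched_rule`, `ambiguity` (comma-joined), `n_matches`.
#' @export
classify_puls <- function(puls, rules = default_rule_table()) {
  if (nrow(puls) == 0L) {
    return(tibble::tibble(pul_id = character(), genome_id = character(),
                          substrate = character(), variant = character(),
                          matched_rule = character(), ambiguity = character(),
                          n_matches = integer()))
  }
  rows <- lapply(seq_len(nrow(puls)), function(i) {
    p <- classify_pul(puls[i, ], rules)
    tibble::tibble(pul_id = p$pul_id, genome_id = puls$genome_id[i],
                   substrate = p$substrate, variant = p$variant,
                   matched_rule = p$matched_rule,
                   ambiguity = paste(p$ambiguity, collapse = ","),
                   n_matches = p$n_matches)
  })
  dplyr::bind_rows(rows)
}

#' Substrate prevalence summary
#'
#' Per substrate: number of PULs, number and integer percentage of
#' genomes (isolates) carrying at least one such PUL, plus per-variant
#' PUL counts.
#'
#' @param predictions output of [classify_puls()] (needs `genome_id`).
#' @param n_genomes total number of genomes surveyed.
#' @return List with tibbles `by_substrate` (`substrate`, `n_puls`,
#'   `n_isolates`, `pct_isolates`) and `by_variant` (`substrate`,
#'   `variant`, `n_puls`).
#' @export
summarize_predictions <- function(predictions, n_genomes) {
  stopifnot(n_genomes >= 0L)
  if (nrow(predictions) == 0L) {
    return(list(
      by_substrate = tibble::tibble(substrate = character(),
                                    n_puls = integer(), n_isolates = integer(),
                                    pct_isolates = numeric()),
      by_variant = tibble::tibble(substrate = character(),
                                  variant = character(), n_puls = integer())))
  }
  by_sub <- dplyr::summarise(
    dplyr::group_by(predictions, .data$substrate),
    n_puls = dplyr::n(),
    n_isolates = dplyr::n_distinct(.data$genome_id),
    .groups = "drop")
  by_sub$pct_isolates <- if (n_genomes > 0L) {
    round(100 * by_sub$n_isolates / n_genomes)
  } else 0
  by_var <- dplyr::summarise(
    dplyr::group_by(predictions, .data$substrate, .data$variant),
    n_puls = dplyr::n(), .groups = "drop")
  list(by_substrate = dplyr::arrange(by_sub, dplyr::desc(.data$n_puls),
                                     .data$substrate),
       by_variant = dplyr::arrange(by_var, .data$substrate, .data$variant))
}
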