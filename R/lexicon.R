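#' Build a cleaned drug lexicon from raw synonym lists
#'
#' Applies the vocabulary-hygiene rules used before text scanning: synonyms
#' are case-folded and whitespace-normalized; dosage-like tokens (a number
#' attached to mg/ml/mcg/g/%) are removed; synonyms shorter than five
#' characters are excluded (short strings like "ASA" cause false substring
#' hits); and a synonym appearing under more than one canonical name is
#' ambiguous and dropped from every entry. An entry whose synonym set
#' becomes empty is retained with its canonical name alone when that name is
#' itself at least five characters, otherwise it lands in the
#' `dropped_entries` attribute.
#'
#' @param raw_synonym_lists Named list: canonical name -> character vector of
#'   raw synonyms.
#' @return A tibble with columns `canonical`, `synonym` (one row per kept
#'   synonym; the canonical name is always included as its own synonym when
#'   long enough), with attribute `dropped_entries`.
#' @examples
#' build_drug_lexicon(list(aspirin = c("ASA", "acetylsalicylic acid")))
#' @export
build_drug_lexicon <- function(raw_synonym_lists) {
  if (length(raw_synonym_lists) == 0L || is.null(names(raw_synonym_lists)) ||
      any(!nzchar(names(raw_synonym_lists)))) {
    abort("`raw_synonym_lists` must be a nonempty named list.",
          class = "pharmgap_config_error")
  }
  entries <- imap(raw_synonym_lists, function(syns, canonical) {
    s <- unique(normalize_term(c(canonical, syns)))
    s <- s[!is_dosage_token(s)]
    s[nchar(s) >= 5L]
  })
  # a synonym shared by several entries is ambiguous: drop it everywhere
  all_syn <- unlist(entries, use.names = FALSE)
  ambiguous <- unique(all_syn[duplicated(all_syn)])
  entries <- map(entries, function(s) setdiff(s, ambiguous))

  dropped <- names(entries)[lengths(entries) == 0L]
  kept <- entries[lengths(entries) > 0L]
  lex <- tibble(
    canonical = rep(normalize_term(names(kept)), lengths(kept)),
    synonym = unlist(kept, use.names = FALSE)
  )
  attr(lex, "dropped_entries") <- dropped
  lex
}

is_dosage_token <- function(x) {
  stringr::str_detect(x, "\\d+(\\.\\d+)?\\s*(mg|ml|mcg|g|%)\\b")
}

#' Normalize a claims drug name to canonical ingredient names
#'
#' Decomposes multi-ingredient product names into individual ingredients and
#' strips non-therapeutic noise: whole-name categories (allergenic extracts,
#' vaccines, prenatal vitamins, lotions, kits) are removed outright; source
#' terms (human, bovine, ...), process/formulation terms (micronized,
#' injection, ...) and salt suffixes (hydrochloride, calcium, ...) are
#' stripped token-wise. Unmatched names pass through lowercased.
#'
#' @param raw_name A single raw product name.
#' @param filter_vocab Term lists as produced by
#'   [default_claims_name_filters()]: `category`, `source`, `process`,
#'   `salt`, and the split `delimiters`.
#' @return Character vector of ingredient names (possibly empty).
#' @examples
#' clean_claims_drug_name("acetaminophen-codeine")
#' clean_claims_drug_name("metformin hydrochloride")
#' clean_claims_drug_name("influenza vaccine")
#' @export
clean_claims_drug_name <- function(raw_name,
                                   filter_vocab = default_claims_name_filters()) {
  if (length(raw_name) != 1L || !nzchar(raw_name)) {
    abort("`raw_name` must be a single nonempty string.",
          class = "pharmgap_config_error")
  }
  name <- normalize_term(raw_name)
  if (matches_any_phrase(name, filter_vocab$category)) return(character())

  delims <- paste(escape_regex(filter_vocab$delimiters), collapse = "|")
  parts <- strsplit(name, delims)[[1]]
  strip <- c(filter_vocab$source, filter_vocab$process, filter_vocab$salt)
  out <- map_chr(parts, function(p) {
    toks <- tokenize(p)
    paste(toks[!toks %in% strip], collapse = " ")
  })
  unique(out[nzchar(out)])
}

#' @rdname clean_claims_drug_name
#' @export
default_claims_name_filters <- function() {
  list(
    delimiters = c("-", "/", ";", " with ", " and "),
    category = c("allergenic extract", "extract", "vaccine", "prenatal vitamin",
                 "prenatal vitamins", "lotion", "kit", "allergen"),
    source = c("human", "bovine", "porcine", "recombinant", "synthetic"),
    process = c("micronized", "injection", "injectable", "solution", "topical",
                "oral", "tablet", "tablets", "capsule", "capsules", "cream",
                "syrup", "suspension", "er", "xr"),
    salt = c("hydrochloride", "hcl", "sodium", "calcium", "potassium",
             "sulfate", "succinate", "tartrate", "bitartrate", "maleate",
             "mesylate", "citrate", "phosphate", "acetate", "besylate",
             "fumarate", "nitrate", "dipropionate", "propionate", "valerate")
  )
}

#' Built-in population lexicon
#'
#' Synonym sets for the closed list of maternal and pediatric population
#' tags used by the annotation scanner.
#'
#' @return A tibble with columns `tag`, `synonym`.
#' @export
default_population_lexicon <- function() {
  syns <- list(
    pregnancy = c("pregnant", "pregnancy", "gestation"),
    labor_delivery = c("childbirth", "parturition"),
    lactation = c("lactation", "breastfeeding"),
    postpartum = c("postpartum", "puerperium"),
    mother = c("mother", "mothers", "maternal"),
    preterm = c("preterm", "premature"),
    neonate = c("neonate", "neonates", "neonatal"),
    newborn = c("newborn", "newborns"),
    infant = c("infant", "infants"),
    children = c("child", "children"),
    adolescent = c("adolescent", "adolescents", "teenager"),
    fetus = c("fetus", "fetal"),
    pediatric = c("pediatric", "paediatric")
  )
  tibble(tag = rep(names(syns), lengths(syns)),
         synonym = unlist(syns, use.names = FALSE))
}

population_tags <- function() {
  c("pregnancy", "labor_delivery", "lactation", "postpartum", "mother",
    "preterm", "neonate", "newborn", "infant", "children", "adolescent",
    "fetus", "pediatric")
}

#' Construct a disease taxonomy restricted to disease/psychiatry MeSH trees
#'
#' Accepts only terms whose tree codes fall under C (diseases) or F
#' (psychiatry and psychology), mirroring the restriction used when
#' collecting disease annotations from MeSH headings.
#'
#' @param term_to_tree Named list or tibble mapping MeSH term -> tree codes.
#' @return A tibble with columns `term`, `tree_code`.
#' @export
disease_taxonomy <- function(term_to_tree) {
  if (is.data.frame(term_to_tree)) {
    tax <- as_tibble(term_to_tree)[, c("term", "tree_code")]
  } else {
    tax <- tibble(term = rep(names(term_to_tree), lengths(term_to_tree)),
                  tree_code = unlist(term_to_tree, use.names = FALSE))
  }
  bad <- !stringr::str_detect(tax$tree_code, "^[CF]")
  if (any(bad)) {
    abort(paste0("Tree codes must start with C or F; offending: ",
                 paste(unique(tax$tree_code[bad]), collapse = ", ")),
          class = "pharmgap_config_error")
  }
  tax
}

#' @rdname disease_taxonomy
#' @export
default_disease_taxonomy <- function() {
  disease_taxonomy(list(
    Asthma = "C08.127.108",
    Hypertension = "C14.907.489",
    Epilepsy = "C10.228.140",
    `Depressive Disorder` = "F03.600.300",
    `Anxiety Disorders` = "F03.080"
  ))
}
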