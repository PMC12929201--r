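#' Write and read abstract records as MEDLINE-like tagged text
#'
#' One record per block, blank-line separated, with `PMID`, `TI`, `AB`,
#' `MH` (one line per MeSH term), `OT` (one line per keyword), `YR`, and
#' `LA` fields.
#'
#' @param records Abstract-record tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); a record tibble (reader).
#' @export
write_corpus_medline <- function(records, path) {
  blocks <- map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    lines <- c(
      paste0("PMID- ", r$record_id),
      paste0("TI  - ", r$title),
      paste0("AB  - ", r$abstract),
      map_chr(r$mesh_terms[[1]], ~ paste0("MH  - ", .x)),
      map_chr(r$keywords[[1]], ~ paste0("OT  - ", .x)),
      paste0("YR  - ", r$year),
      paste0("LA  - ", r$language %||% "eng")
    )
    paste(lines, collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' @rdname write_corpus_medline
#' @export
read_corpus_medline <- function(path) {
  txt <- readLines(path)
  block_id <- cumsum(c(TRUE, !nzchar(txt)[-length(txt)]))
  blocks <- split(txt[nzchar(txt)], block_id[nzchar(txt)])
  first_or <- function(x, default) if (length(x)) x[[1]] else default
  rows <- map(blocks, function(b) {
    tag <- substr(b, 1L, 4L)
    val <- sub("^.{6}", "", b)
    tibble(
      record_id = first_or(val[tag == "PMID"], NA_character_),
      title = first_or(val[tag == "TI  "], ""),
      abstract = first_or(val[tag == "AB  "], ""),
      mesh_terms = list(val[tag == "MH  "]),
      keywords = list(val[tag == "OT  "]),
      year = as.integer(first_or(val[tag == "YR  "], NA)),
      language = first_or(val[tag == "LA  "], "eng")
    )
  })
  bind_rows(rows)
}

#' JSON-lines writers and readers for tabular outputs
#'
#' Each row becomes one JSON object per line; list-columns round-trip as
#' JSON arrays.
#'
#' @param df A data frame.
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_jsonl <- function(df, path) {
  lines <- map_chr(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, null = "null",
                     digits = NA)
  })
  # single-row slices wrap scalars in length-1 arrays; unwrap via fromJSON on read
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  rows <- map(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    as_tibble(map(x, function(v) {
      if (length(v) == 1L && !is.list(v)) v else list(v)
    }))
  })
  bind_rows(rows)
}

#' Read and write drug lexicons
#'
#' Lexicons travel as two-column TSV (`canonical`, `synonym`) or as JSON
#' (canonical name -> synonym array).
#'
#' @param lexicon Lexicon tibble ([build_drug_lexicon()]).
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return `path` invisibly (writer); a lexicon tibble (reader).
#' @export
write_lexicon <- function(lexicon, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(lexicon[, c("canonical", "synonym")], path)
  } else {
    by_canon <- split(lexicon$synonym, lexicon$canonical)
    jsonlite::write_json(by_canon, path, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as_tibble(readr::read_tsv(path, show_col_types = FALSE,
                              col_types = "cc"))
  } else {
    x <- jsonlite::fromJSON(path)
    tibble(canonical = rep(names(x), lengths(x)),
           synonym = unlist(x, use.names = FALSE))
  }
}

#' Read a labeled corpus in JSON-lines or delimited layout
#'
#' The delimited dialect is configurable through a column map so released
#' corpora with arbitrary headers can be ingested; labels are parsed from a
#' separator-joined string column (e.g. `"PK|PE"`), with empty/`NA`
#' meaning non-relevant.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"delim"`.
#' @param col_map Named character vector mapping the standard fields
#'   (`record_id`, `title`, `abstract`, `labels`) to file columns.
#' @param delim Field delimiter for the delimited dialect.
#' @param label_sep Separator inside the labels column.
#' @return Labeled-corpus tibble with `relevant` and `study_types`
#'   (list-column) alongside the text fields.
#' @export
read_labeled_corpus <- function(path, format = c("jsonl", "delim"),
                                col_map = c(record_id = "record_id",
                                            title = "title",
                                            abstract = "abstract",
                                            labels = "labels"),
                                delim = "\t", label_sep = "|") {
  format <- match.arg(format)
  raw <- if (format == "jsonl") {
    read_jsonl(path)
  } else {
    as_tibble(readr::read_delim(path, delim = delim, show_col_types = FALSE))
  }
  df <- tibble(
    record_id = as.character(raw[[col_map[["record_id"]]]]),
    title = as.character(raw[[col_map[["title"]]]]),
    abstract = as.character(raw[[col_map[["abstract"]]]]),
    labels_raw = as.character(raw[[col_map[["labels"]]]])
  )
  df |>
    mutate(
      study_types = map(.data$labels_raw, function(s) {
        if (is.na(s) || !nzchar(s)) character()
        else intersect(strsplit(s, label_sep, fixed = TRUE)[[1]], STUDY_TYPES)
      }),
      relevant = lengths(.data$study_types) > 0L,
      mesh_terms = list(character()), keywords = list(character())
    ) |>
    select(-"labels_raw")
}

#' Export annotations in the relational four-table layout
#'
#' Splits annotation results into the `pmid2drug`, `pmid2pop`,
#' `pmid2disease`, and `pmid2studytype` long tables; optionally writes each
#' as TSV into `dir`.
#'
#' @param annotations Output of [annotate_corpus()].
#' @param dir Optional output directory.
#' @return Named list of four tibbles.
#' @export
annotations_to_tables <- function(annotations, dir = NULL) {
  long <- function(col, out_name) {
    annotations |>
      select("record_id", all_of(col)) |>
      unnest(all_of(col)) |>
      setNames(c("pmid", out_name))
  }
  tabs <- list(
    pmid2drug = long("drugs", "drug"),
    pmid2pop = long("populations", "population"),
    pmid2disease = long("diseases", "disease"),
    pmid2studytype = long("study_types", "study_type")
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    imap(tabs, ~ readr::write_tsv(.x, file.path(dir, paste0(.y, ".tsv"))))
  }
  tabs
}
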