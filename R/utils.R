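# internal helpers shared across modules

# whitespace tokenizer used by triage text assembly and the reference classifier
tokenize <- function(text) {
  out <- strsplit(trimws(text), "\\s+")[[1]]
  out[nzchar(out)]
}

# case-insensitive word-boundary match of any phrase in `phrases` inside `text`
matches_any_phrase <- function(text, phrases) {
  if (length(phrases) == 0L || !nzchar(text)) return(FALSE)
  pat <- paste0("\\b(", paste(escape_regex(phrases), collapse = "|"), ")\\b")
  stringr::str_detect(stringr::str_to_lower(text), pat)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# squash internal whitespace and case-fold; lexicon normal form
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "pharmgap_config_error")
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single nonnegative integer.", name),
          class = "pharmgap_config_error")
  }
  invisible(as.integer(x))
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
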