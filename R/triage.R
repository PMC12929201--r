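#' Assemble a record's text and split it into fixed-length token chunks
#'
#' Concatenates title, abstract, MeSH terms, and keywords (in that order,
#' single-space separated), tokenizes on whitespace, and cuts the token
#' stream into non-overlapping chunks of exactly `max_chunk_len` tokens
#' except possibly the last, mirroring how transformer-length limits are
#' handled. An empty record yields a single empty chunk.
#'
#' @param record One-row tibble or named list with `record_id`, `title`,
#'   `abstract`, `mesh_terms`, `keywords`.
#' @param max_chunk_len Maximum tokens per chunk (>= 1).
#' @return List of class `text_sample` with `record_id` and `chunks` (list
#'   of token vectors).
#' @export
assemble_and_chunk <- function(record, max_chunk_len = 512L) {
  if (!is.numeric(max_chunk_len) || max_chunk_len < 1) {
    abort("`max_chunk_len` must be >= 1.", class = "pharmgap_config_error")
  }
  rec <- record_as_list(record)
  text <- paste(rec$title, rec$abstract,
                paste(rec$mesh_terms, collapse = " "),
                paste(rec$keywords, collapse = " "))
  toks <- tokenize(text)
  if (length(toks) == 0L) {
    chunks <- list(character())
  } else {
    grp <- (seq_along(toks) - 1L) %/% max_chunk_len
    chunks <- unname(split(toks, grp))
  }
  structure(list(record_id = rec$record_id, chunks = chunks),
            class = "text_sample")
}

record_as_list <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    list(record_id = record$record_id, title = record$title,
         abstract = record$abstract,
         mesh_terms = record$mesh_terms[[1]], keywords = record$keywords[[1]])
  } else {
    list(record_id = record$record_id, title = record$title %||% "",
         abstract = record$abstract %||% "",
         mesh_terms = record$mesh_terms %||% character(),
         keywords = record$keywords %||% character())
  }
}

# chunked text per record, as a tibble (one row per chunk)
chunk_corpus <- function(records, max_chunk_len = 512L) {
  rows <- map(seq_len(nrow(records)), function(i) {
    ts <- assemble_and_chunk(records[i, ], max_chunk_len)
    tibble(record_id = ts$record_id,
           chunk_index = seq_along(ts$chunks),
           text = map_chr(ts$chunks, paste, collapse = " "))
  })
  bind_rows(rows)
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fp,fn,tn Confusion-matrix cell counts.
#' @return One-row tibble with `accuracy`, `precision`, `recall`, `f1`
#'   (each 0 when its denominator is 0).
#' @export
eval_metrics <- function(tp, fp, fn, tn) {
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  tibble(
    accuracy = safe_div(tp + tn, tp + fp + fn + tn),
    precision = precision,
    recall = recall,
    f1 = if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  )
}

#' Reference study-type classifier: regularized logistic regression on
#' token counts
#'
#' Factory for the pluggable classifier interface used by
#' [crossval_evaluate()]: calling it returns a fresh classifier with `fit`
#' (texts + binary labels) and `predict` (texts -> probabilities) closures.
#' Internally a sparse document-term count matrix feeds a binomial glmnet
#' fit evaluated at a single fixed regularization constant. Any classifier
#' honoring the same two-function contract (for example a transformer
#' wrapper) can be substituted.
#'
#' @param lambda Ridge/lasso penalty at which the glmnet path is evaluated.
#' @param min_count Minimum training-corpus token frequency for a token to
#'   enter the vocabulary.
#' @return A list with `fit(texts, y)` and `predict(model, texts)`.
#' @export
token_count_classifier <- function(lambda = 0.01, min_count = 2L) {
  list(
    fit = function(texts, y) {
      toks <- strsplit(stringr::str_to_lower(texts), "\\s+")
      tab <- table(unlist(toks))
      vocab <- names(tab)[tab >= min_count]
      X <- doc_term_matrix(toks, vocab)
      fit <- glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)),
                            family = "binomial", lambda = lambda,
                            alpha = 0)
      list(vocab = vocab, fit = fit, lambda = lambda)
    },
    predict = function(model, texts) {
      toks <- strsplit(stringr::str_to_lower(texts), "\\s+")
      X <- doc_term_matrix(toks, model$vocab)
      as.numeric(predict(model$fit, X, s = model$lambda, type = "response"))
    }
  )
}

doc_term_matrix <- function(token_lists, vocab) {
  j <- match(unlist(token_lists), vocab)
  i <- rep(seq_along(token_lists), lengths(token_lists))
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(length(token_lists), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Cross-validated evaluation of a one-vs-non-relevant study-type classifier
#'
#' Frames the binary task as records positive for `study_type` versus
#' non-relevant records, splits them into stratified folds with a fixed
#' seed, trains the injected classifier on chunked text (every chunk
#' inherits its record's label), and scores held-out records by max-pooling
#' chunk probabilities, so each record is predicted exactly once as a
#' held-out item. Metrics are reported per fold and pooled over the
#' combined held-out confusion matrix.
#'
#' @param corpus Labeled corpus tibble: record fields plus `relevant`
#'   (logical) and `study_types` (list-column).
#' @param study_type One of `"PK"`, `"PE"`, `"CT"`.
#' @param classifier_factory Function returning a fit/predict pair, e.g.
#'   [token_count_classifier()] (the default).
#' @param k_folds Number of folds (>= 2).
#' @param seed Seed controlling the stratified shuffle.
#' @param max_chunk_len Chunk length passed to [assemble_and_chunk()].
#' @param threshold Probability cutoff for a positive record call.
#' @return Object of class `triage_cv` with `fold_metrics`, `pooled`
#'   metrics, and per-record `predictions`.
#' @export
crossval_evaluate <- function(corpus, study_type,
                              classifier_factory = token_count_classifier,
                              k_folds = 3L, seed = 1L,
                              max_chunk_len = 512L, threshold = 0.5) {
  stopifnot(study_type %in% STUDY_TYPES)
  if (k_folds < 2L) {
    abort("`k_folds` must be >= 2.", class = "pharmgap_config_error")
  }
  corpus <- as_tibble(corpus)
  is_pos <- corpus$relevant & map_lgl(corpus$study_types, ~ study_type %in% .x)
  is_neg <- !corpus$relevant
  sub <- corpus[is_pos | is_neg, ]
  y <- is_pos[is_pos | is_neg]
  for (cls in c(TRUE, FALSE)) {
    if (!any(y == cls)) {
      abort(sprintf("No %s examples for study type %s.",
                    if (cls) "positive" else "negative", study_type),
            class = "pharmgap_data_error")
    }
  }

  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })

  chunks <- chunk_corpus(sub, max_chunk_len)
  chunk_fold <- folds[match(chunks$record_id, sub$record_id)]
  chunk_y <- y[match(chunks$record_id, sub$record_id)]

  preds <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    clf <- classifier_factory()
    model <- clf$fit(chunks$text[chunk_fold != f], chunk_y[chunk_fold != f])
    test <- chunks[chunk_fold == f, ]
    score <- clf$predict(model, test$text)
    pooled <- tibble(record_id = test$record_id, score = score) |>
      summarise(prob = max(.data$score), .by = "record_id")
    preds[[f]] <- pooled |>
      mutate(fold = f, truth = y[match(.data$record_id, sub$record_id)],
             pred = .data$prob >= threshold)
  }
  predictions <- bind_rows(preds)

  metr <- function(df) {
    eval_metrics(tp = sum(df$pred & df$truth), fp = sum(df$pred & !df$truth),
                 fn = sum(!df$pred & df$truth), tn = sum(!df$pred & !df$truth))
  }
  fold_metrics <- predictions |>
    group_by(.data$fold) |>
    group_modify(~ metr(.x)) |>
    ungroup()

  structure(
    list(study_type = study_type, k_folds = k_folds, seed = seed,
         fold_metrics = fold_metrics, pooled = metr(predictions),
         predictions = predictions),
    class = "triage_cv"
  )
}

#' @export
print.triage_cv <- function(x, ...) {
  cat("<triage_cv>", x$study_type, "|", x$k_folds, "folds | pooled F1",
      round(x$pooled$f1, 3), "\n")
  invisible(x)
}

#' Calibration: re-review misclassified items and recompute metrics
#'
#' Collects the record ids where prediction and current label disagree,
#' passes them to a review function (a human curator in practice, a
#' ground-truth oracle in tests), replaces the labels it returns, and
#' reports metrics before and after. The review function may only alter ids
#' in the misclassified set.
#'
#' @param predictions Tibble (`record_id`, `label` logical): predicted labels.
#' @param truth Tibble (`record_id`, `label` logical): current labels.
#' @param review_fn Function taking the misclassified ids and returning a
#'   tibble (`record_id`, `label`) of corrected labels.
#' @return List with `corrected` labels, `before`/`after` metric rows,
#'   `delta` (after minus before), and `reviewed_ids`.
#' @export
calibration_pass <- function(predictions, truth, review_fn) {
  predictions <- as_tibble(predictions)
  truth <- as_tibble(truth)
  if (!setequal(predictions$record_id, truth$record_id)) {
    abort("predictions and truth must cover the same record ids.",
          class = "pharmgap_data_error")
  }
  truth <- truth[match(predictions$record_id, truth$record_id), ]
  metr <- function(lbl) {
    eval_metrics(tp = sum(predictions$label & lbl),
                 fp = sum(predictions$label & !lbl),
                 fn = sum(!predictions$label & lbl),
                 tn = sum(!predictions$label & !lbl))
  }
  before <- metr(truth$label)
  mis_ids <- predictions$record_id[predictions$label != truth$label]
  corrected <- truth
  if (length(mis_ids) > 0L) {
    review <- as_tibble(review_fn(mis_ids))
    extra <- setdiff(review$record_id, mis_ids)
    if (length(extra) > 0L) {
      abort(paste0("review_fn altered ids outside the misclassified set: ",
                   paste(extra, collapse = ", ")),
            class = "pharmgap_invariant_error")
    }
    idx <- match(review$record_id, corrected$record_id)
    corrected$label[idx] <- review$label
  }
  after <- metr(corrected$label)
  list(corrected = corrected, before = before, after = after,
       delta = after - before, reviewed_ids = mis_ids)
}

#' Inter-annotator agreement and third-curator adjudication
#'
#' Agreement is counted on full label tuples (relevance plus the study-type
#' set), the strict definition. Where the two curators agree, their label
#' stands; every disagreement must be adjudicated by the third curator.
#'
#' @param labels_a,labels_b Tibbles (`record_id`, `relevant`, `study_types`
#'   list-column) covering identical id sets.
#' @param labels_c Adjudicator labels covering at least the disagreements.
#' @return List with `report` (n_items, n_agree, agreement_rate,
#'   disagreement_ids) and `final` labels tibble.
#' @export
agreement_and_adjudicate <- function(labels_a, labels_b, labels_c) {
  a <- as_tibble(labels_a); b <- as_tibble(labels_b); c3 <- as_tibble(labels_c)
  if (!setequal(a$record_id, b$record_id)) {
    abort("labels_a and labels_b must cover identical record ids.",
          class = "pharmgap_data_error")
  }
  b <- b[match(a$record_id, b$record_id), ]
  key <- function(df) {
    paste(df$relevant, map_chr(df$study_types, ~ paste(sort(.x), collapse = "+")))
  }
  agree <- key(a) == key(b)
  dis_ids <- a$record_id[!agree]
  missing <- setdiff(dis_ids, c3$record_id)
  if (length(missing) > 0L) {
    abort(paste0("Missing adjudication for: ", paste(missing, collapse = ", ")),
          class = "pharmgap_data_error")
  }
  final <- a
  if (length(dis_ids) > 0L) {
    idx <- match(dis_ids, a$record_id)
    cidx <- match(dis_ids, c3$record_id)
    final$relevant[idx] <- c3$relevant[cidx]
    final$study_types[idx] <- c3$study_types[cidx]
  }
  report <- list(n_items = nrow(a), n_agree = sum(agree),
                 agreement_rate = sum(agree) / nrow(a),
                 disagreement_ids = dis_ids)
  list(report = report, final = final)
}

#' Corpus inclusion rule: positive in at least one study type
#'
#' @param per_type_predictions Named logical vector (or one-row data frame)
#'   with entries `PK`, `PE`, `CT`.
#' @return `TRUE` iff any study type is predicted positive.
#' @export
inclusion_rule <- function(per_type_predictions) {
  p <- unlist(per_type_predictions)
  if (!all(STUDY_TYPES %in% names(p))) {
    abort("All of PK, PE, CT must be present.", class = "pharmgap_config_error")
  }
  any(as.logical(p[STUDY_TYPES]))
}
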