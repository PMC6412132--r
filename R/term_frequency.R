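# Term-frequency table: unique genes per category whose knowledge-base text
# matches each word set.

#' Load word sets
#'
#' Word sets are YAML config (label + member words, stored lowercase); the
#' packaged default groups common functional vocabulary (membrane,
#' transport, enzyme, ... ) into sets of similar words.
#'
#' @param path YAML file; `NULL` loads the packaged default
#' @return list of `list(label, words)`
#' @export
load_word_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "word_sets.yaml", package = "yome")
  stop_missing_file(path, "word sets")
  ws <- yaml::read_yaml(path)$word_sets
  lapply(ws, function(w) {
    words <- tolower(unlist(w$words))
    stopifnot(length(words) > 0, all(nzchar(words)))
    list(label = w$label, words = words)
  })
}

tokenize_words <- function(x) {
  toks <- unlist(strsplit(tolower(x), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

#' Count unique genes matching each word set, by category
#'
#' Feature values of the scanned types are tokenized on non-alphanumerics
#' and matched case-insensitively on whole words. A gene counts at most
#' once per word set no matter how many member words or features match.
#'
#' @param features data.frame with gene_id, feature_type, value (e.g. a
#'   feature store's `features`)
#' @param categories finalized category table (gene_id, category)
#' @param word_sets from [load_word_sets()]
#' @param feature_types which feature types to scan (default description
#'   and summary)
#' @return data.frame: word_set, yome, well_annotated, excluded
#' @export
count_word_sets <- function(features, categories, word_sets = load_word_sets(),
                            feature_types = c("description", "summary")) {
  f <- features[features$feature_type %in% feature_types &
                  features$gene_id %in% categories$gene_id, , drop = FALSE]
  cat_map <- stats::setNames(categories$category, categories$gene_id)
  tokens_by_gene <- lapply(split(f$value, f$gene_id),
                           function(v) unique(tokenize_words(v)))
  gene_ids <- names(tokens_by_gene)
  gene_cats <- cat_map[gene_ids]
  rows <- lapply(word_sets, function(ws) {
    hit <- vapply(tokens_by_gene, function(tok) any(tok %in% ws$words), logical(1))
    counts <- table(factor(gene_cats[hit], levels = final_categories()))
    data.frame(word_set = ws$label,
               yome = as.integer(counts["yome"]),
               well_annotated = as.integer(counts["well_annotated"]),
               excluded = as.integer(counts["excluded"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
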