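# Per-knowledge-base categorization: keyword rules + structured-data rules.

#' Load a categorization rule set
#'
#' Rule sets are YAML config (see `inst/extdata/rules.yaml` for the shipped
#' default): a list of keyword rules (kb, feature_type, pattern, target,
#' match_mode), toggles for the structured rules, and the no-information
#' phrase list. Patterns are stored lowercase; matching is case-insensitive.
#'
#' @param path YAML file; `NULL` loads the packaged default
#' @return list of class `yome_rules` with elements `keyword_rules`
#'   (data.frame incl. generated `rule_id`), `structured`, `no_info_phrases`,
#'   `no_info_feature_types`
#' @export
load_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rules.yaml", package = "yome")
  stop_missing_file(path, "rule set")
  cfg <- yaml::read_yaml(path)
  kr <- do.call(rbind, lapply(cfg$keyword_rules, function(r) {
    stopifnot(nzchar(r$pattern))
    data.frame(kb = r$kb, feature_type = r$feature_type,
               pattern = tolower(r$pattern),
               target = r$target,
               match_mode = r$match_mode %||% "substring",
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(kr$kb %in% yome_kbs()),
            all(kr$feature_type %in% yome_feature_types()),
            all(kr$target %in% yome_categories()),
            all(kr$match_mode %in% c("substring", "word")))
  kr$rule_id <- sprintf("%s.%s.%s", kr$kb, kr$feature_type,
                        gsub("[^a-z0-9]+", "_", kr$pattern))
  structure(
    list(keyword_rules = kr,
         structured = cfg$structured_rules,
         no_info_phrases = tolower(unlist(cfg$no_info_phrases)),
         no_info_feature_types = unlist(cfg$no_info_feature_types)),
    class = "yome_rules"
  )
}

#' Apply keyword rules to a single feature
#'
#' Returns every rule that matches the feature's value (case-insensitive,
#' respecting each rule's match mode); an empty result is a valid outcome.
#'
#' @param feature list or one-row data.frame with `kb`, `feature_type`,
#'   `value` (or `feature_value`)
#' @param rules a `yome_rules` object
#' @return data.frame with columns `category`, `rule_id` (zero rows if no
#'   rule fires)
#' @export
classify_feature <- function(feature, rules) {
  value <- feature$value %||% feature$feature_value
  kr <- rules$keyword_rules
  kr <- kr[kr$kb == feature$kb & kr$feature_type == feature$feature_type, , drop = FALSE]
  if (nrow(kr) == 0) return(data.frame(category = character(), rule_id = character()))
  v <- tolower(value)
  hit <- vapply(seq_len(nrow(kr)), function(i) {
    if (kr$match_mode[i] == "word") {
      grepl(paste0("\\b", escape_regex(kr$pattern[i]), "\\b"), v)
    } else {
      grepl(kr$pattern[i], v, fixed = TRUE)
    }
  }, logical(1))
  data.frame(category = kr$target[hit], rule_id = kr$rule_id[hit],
             stringsAsFactors = FALSE)
}

escape_regex <- function(x) gsub("([\\^$.|?*+(){}\\[\\]\\\\])", "\\\\\\1", x)

#' Annotation-score rule
#'
#' Maps a protein annotation score (integer 1-5) to a category: scores of
#' two or below indicate the y-ome, four or above well-annotated, and a
#' score of exactly three carries not enough information for automated
#' assignment.
#'
#' @param score integer in 1..5
#' @return one of "yome", "insufficient", "well_annotated"
#' @export
uniprot_score_rule <- function(score) {
  score <- suppressWarnings(as.integer(score))
  if (length(score) != 1 || is.na(score) || score < 1 || score > 5) {
    stop("annotation score must be a single integer in 1..5", call. = FALSE)
  }
  if (score <= 2) "yome" else if (score == 3) "insufficient" else "well_annotated"
}

#' Structured (non-keyword) rules for one gene in one knowledge base
#'
#' Fires well_annotated for reaction-equation, complex or insertion-element
#' annotations (including primary names beginning "ins" in ecocyc), excluded
#' for pseudogene/phantom flags and for ecogene primary names ending in an
#' apostrophe, and applies the annotation-score rule for uniprot.
#'
#' @param features data.frame of the gene's features in one kb
#'   (`feature_type`, `value`)
#' @param kb the knowledge-base name
#' @param primary_name the gene's primary name as recorded by that source
#' @param rules a `yome_rules` object
#' @return data.frame with columns `category`, `rule_id`
#' @export
structured_rules <- function(features, kb, primary_name, rules) {
  sw <- rules$structured
  out <- list()
  add <- function(category, rule_id) {
    out[[length(out) + 1L]] <<- data.frame(category = category, rule_id = rule_id,
                                           stringsAsFactors = FALSE)
  }
  has <- function(ft) any(features$feature_type == ft)
  if (kb == "ecocyc") {
    if (isTRUE(sw$ecocyc_reaction_equation) && has("reaction_equation"))
      add("well_annotated", "ecocyc.structured.reaction_equation")
    if (isTRUE(sw$ecocyc_complex) && has("complex"))
      add("well_annotated", "ecocyc.structured.complex")
    if (isTRUE(sw$ecocyc_insertion) && has("insertion_flag"))
      add("well_annotated", "ecocyc.structured.insertion_flag")
    if (isTRUE(sw$ecocyc_ins_name) && grepl("^ins", primary_name))
      add("well_annotated", "ecocyc.structured.ins_name")
  }
  if (kb == "uniprot" && isTRUE(sw$uniprot_annotation_score)) {
    scores <- features$value[features$feature_type == "annotation_score"]
    for (s in scores) {
      cat <- uniprot_score_rule(s)
      if (cat == "yome") add("yome", "uniprot.structured.annotation_score_low")
      if (cat == "well_annotated") add("well_annotated", "uniprot.structured.annotation_score_high")
    }
  }
  if (isTRUE(sw$pseudogene_flag) && has("pseudogene_flag"))
    add("excluded", paste0(kb, ".structured.pseudogene_flag"))
  if (isTRUE(sw$phantom_flag) && has("phantom_flag"))
    add("excluded", paste0(kb, ".structured.phantom_flag"))
  if (kb == "ecogene" && isTRUE(sw$ecogene_apostrophe) &&
      grepl("['’]$", primary_name))
    add("excluded", "ecogene.structured.apostrophe")
  if (length(out) == 0) return(data.frame(category = character(), rule_id = character()))
  unique(do.call(rbind, out))
}

#' Categorize one gene within one knowledge base
#'
#' Collects every keyword and structured rule that fires on the gene's
#' features and resolves them by the within-source precedence
#' excluded > well_annotated > yome; when nothing fires the gene has not
#' enough information for automated assignment (`insufficient`). All fired
#' rules are recorded regardless of which one decides.
#'
#' @param gene_id gene identifier
#' @param kb knowledge-base name
#' @param features the gene's features in this kb (data.frame with
#'   `feature_type`, `value`)
#' @param primary_name the per-source primary name
#' @param rules a `yome_rules` object
#' @return list with `gene_ref`, `kb`, `category`, `fired_rules` (character)
#' @export
classify_gene_kb <- function(gene_id, kb, features, primary_name, rules) {
  fired <- list(structured_rules(features, kb, primary_name, rules))
  for (i in seq_len(nrow(features))) {
    fired[[length(fired) + 1L]] <- classify_feature(
      list(kb = kb, feature_type = features$feature_type[i],
           value = features$value[i]), rules)
  }
  fired <- do.call(rbind, fired)
  if (nrow(fired) == 0) {
    return(list(gene_ref = gene_id, kb = kb, category = "insufficient",
                fired_rules = character(0)))
  }
  rk <- category_rank()
  category <- names(rk)[max(rk[fired$category])]
  list(gene_ref = gene_id, kb = kb, category = category,
       fired_rules = unique(fired$rule_id))
}

#' Categorize every gene in a feature store, per knowledge base
#'
#' Vectorized application of [classify_gene_kb()] over a whole store. By
#' default the refseq source is ingested but not categorized (it is carried
#' for comparison only); pass it in `kbs` to include it.
#'
#' @param store a `feature_store`
#' @param rules a `yome_rules` object (default: packaged rules)
#' @param kbs knowledge bases to categorize
#' @return data.frame with columns gene_id, kb, category, fired_rules
#'   (semicolon-separated rule ids)
#' @export
categorize_store <- function(store, rules = load_rules(),
                             kbs = c("ecocyc", "ecogene", "uniprot", "regulondb")) {
  feats <- store$features[store$features$kb %in% kbs, , drop = FALSE]
  kb_names <- attr(store$genes, "kb_names")
  pairs <- unique(feats[, c("gene_id", "kb")])
  if (nrow(pairs) == 0) {
    return(data.frame(gene_id = character(), kb = character(),
                      category = character(), fired_rules = character()))
  }
  key <- function(g, k) paste(g, k, sep = "\r")

  # keyword rules, vectorized over features
  kr <- rules$keyword_rules[rules$keyword_rules$kb %in% kbs, , drop = FALSE]
  vlow <- tolower(feats$value)
  matches <- list()
  for (i in seq_len(nrow(kr))) {
    idx <- feats$kb == kr$kb[i] & feats$feature_type == kr$feature_type[i]
    if (!any(idx)) next
    hit <- if (kr$match_mode[i] == "word") {
      grepl(paste0("\\b", escape_regex(kr$pattern[i]), "\\b"), vlow[idx])
    } else {
      grepl(kr$pattern[i], vlow[idx], fixed = TRUE)
    }
    if (!any(hit)) next
    sel <- which(idx)[hit]
    matches[[length(matches) + 1L]] <- data.frame(
      gene_id = feats$gene_id[sel], kb = feats$kb[sel],
      category = kr$target[i], rule_id = kr$rule_id[i],
      stringsAsFactors = FALSE)
  }

  # structured rules per (gene, kb)
  pn_map <- stats::setNames(kb_names$primary_name,
                            key(kb_names$gene_id, kb_names$kb))
  reg_names <- stats::setNames(store$genes$primary_name, store$genes$gene_id)
  split_feats <- split(feats, key(feats$gene_id, feats$kb))
  for (k in names(split_feats)) {
    f <- split_feats[[k]]
    pn <- pn_map[k]
    if (is.na(pn)) pn <- reg_names[f$gene_id[1]] %||% ""
    if (is.na(pn)) pn <- ""
    sr <- structured_rules(f, f$kb[1], pn, rules)
    if (nrow(sr) > 0) {
      matches[[length(matches) + 1L]] <- data.frame(
        gene_id = f$gene_id[1], kb = f$kb[1],
        category = sr$category, rule_id = sr$rule_id,
        stringsAsFactors = FALSE)
    }
  }

  matches <- do.call(rbind, matches)
  rk <- category_rank()
  out <- pairs
  out$category <- "insufficient"
  out$fired_rules <- ""
  if (!is.null(matches) && nrow(matches) > 0) {
    mk <- key(matches$gene_id, matches$kb)
    agg_cat <- tapply(rk[matches$category], mk, max)
    agg_rules <- tapply(matches$rule_id, mk,
                        function(x) paste(unique(x), collapse = ";"))
    pk <- key(out$gene_id, out$kb)
    got <- pk %in% names(agg_cat)
    out$category[got] <- names(rk)[agg_cat[pk[got]]]
    out$fired_rules[got] <- agg_rules[pk[got]]
  }
  rownames(out) <- NULL
  out
}
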