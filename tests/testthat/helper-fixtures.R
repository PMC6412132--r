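# Shared fixtures and independent oracles, built in code at test time.

feature_row <- function(kb, locus_tag, primary_name, feature_type, feature_value,
                        synonyms = "") {
  data.frame(kb = kb, locus_tag = locus_tag, primary_name = primary_name,
             synonyms = synonyms, feature_type = feature_type,
             feature_value = feature_value, stringsAsFactors = FALSE)
}

write_feature_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Build a feature store directly from a list of feature_row data.frames.
store_from_rows <- function(rows) {
  paths <- list()
  df <- do.call(rbind, rows)
  for (kb in unique(df$kb)) {
    paths[[kb]] <- write_feature_tsv(list(df[df$kb == kb, , drop = FALSE]))
  }
  ingest_kb_tables(paths)
}

# One-gene-per-row category table for the downstream analyses.
category_table <- function(gene_id, category, primary_name = gene_id) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, primary_name = primary_name,
             category = category,
             basis = rep("agreement", n), no_info = rep(FALSE, n),
             low_confidence = rep(FALSE, n), fired_rules = rep("", n),
             stringsAsFactors = FALSE)
}

assignment_rows <- function(kb, category, fired_rules = character(length(kb))) {
  data.frame(kb = kb, category = category,
             fired_rules = rep(fired_rules, length.out = length(kb)),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Independent consensus oracle: a plain-prose if/else enumeration over bare
# per-source category states (well / yome / insufficient / excluded /
# absent). With bare states no rule-id-keyed exception (evidence, strong TF
# evidence, insertion) can apply; the source-pair exception is decidable
# from states alone.
oracle_consensus <- function(states) {
  present <- states[states != "absent"]
  if (length(present) == 0) return(NULL)
  if (any(present == "excluded")) {
    return(list(category = "excluded", basis = "agreement"))
  }
  if (identical(unname(states["ecocyc"]), "well_annotated") &&
      identical(unname(states["uniprot"]), "well_annotated")) {
    return(list(category = "well_annotated", basis = "exception_ecocyc_uniprot"))
  }
  definite <- present[present != "insufficient"]
  if (length(definite) == 0) {
    return(list(category = "yome", basis = "agreement"))
  }
  if (length(unique(definite)) == 1) {
    return(list(category = definite[[1]], basis = "agreement"))
  }
  list(category = NA_character_, basis = "unresolved")
}

# Independent within-source precedence oracle: excluded > well_annotated >
# yome over the set of fired targets, insufficient when nothing fired.
oracle_precedence <- function(fired_targets) {
  if (length(fired_targets) == 0) return("insufficient")
  if ("excluded" %in% fired_targets) return("excluded")
  if ("well_annotated" %in% fired_targets) return("well_annotated")
  "yome"
}

# Toy rule set with n one-word keyword rules on one source/feature type.
toy_rules <- function(targets) {
  base <- load_rules()
  n <- length(targets)
  base$keyword_rules <- data.frame(
    kb = "ecocyc", feature_type = "description",
    pattern = paste0("kw", seq_len(n)),
    target = targets, match_mode = "word",
    rule_id = paste0("ecocyc.description.kw", seq_len(n)),
    stringsAsFactors = FALSE)
  base
}
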