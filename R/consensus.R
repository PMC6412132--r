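# Consensus resolution: agreement across knowledge bases, four exception
# heuristics for high-trust evidence, manual-override layer, and the
# no-information flag.

# rule-id signatures the exception heuristics key on
EVIDENCE_RULE_RE  <- "^ecocyc\\.evidence\\."
REGULONDB_RULE_RE <- "^regulondb\\.tf_evidence\\."
INSERTION_RULE_RE <- "^ecocyc\\.structured\\.(insertion_flag|ins_name)$"

#' Combine per-source category assignments for one gene
#'
#' Evaluation order:
#' 1. any excluded assignment (pseudogene/phantom track) decides `excluded`;
#' 2. assay-grade functional evidence in the primary encyclopedia
#'    (`exception_evidence`) decides well_annotated;
#' 3. experimentally supported ("Strong") transcription-factor evidence
#'    (`exception_regulondb`) decides well_annotated;
#' 4. the encyclopedia and the protein knowledge base both well-annotated
#'    (`exception_ecocyc_uniprot`) decides well_annotated;
#' 5. insertion elements (`exception_insertion`) decide well_annotated;
#' 6. agreement: all definite votes (not `insufficient`) identical decides
#'    that category; no definite vote at all defaults to yome with a
#'    low-confidence flag (absence of evidence is the y-ome's definition);
#' 7. definite votes disagree: the manual override decides (`manual`) if
#'    present, otherwise the gene is `unresolved`.
#'
#' `basis` records the first step that decided. Exclusion is evaluated
#' before the well-annotated exceptions so evidence rules can never
#' resurrect a pseudogene.
#'
#' @param assignments data.frame of the gene's per-source assignments with
#'   columns `kb`, `category`, `fired_rules` (semicolon-separated ids)
#' @param override optional category from the manual-override table
#' @return list with `category`, `basis`, `low_confidence`
#' @export
apply_consensus <- function(assignments, override = NULL) {
  if (nrow(assignments) == 0) stop("at least one assignment is required")
  fired <- unlist(strsplit(assignments$fired_rules, ";", fixed = TRUE))
  res <- function(category, basis, low = FALSE)
    list(category = category, basis = basis, low_confidence = low)

  if (any(assignments$category == "excluded"))
    return(res("excluded", "agreement"))
  if (any(grepl(EVIDENCE_RULE_RE, fired)))
    return(res("well_annotated", "exception_evidence"))
  if (any(grepl(REGULONDB_RULE_RE, fired)))
    return(res("well_annotated", "exception_regulondb"))
  well_kbs <- assignments$kb[assignments$category == "well_annotated"]
  if (all(c("ecocyc", "uniprot") %in% well_kbs))
    return(res("well_annotated", "exception_ecocyc_uniprot"))
  if (any(grepl(INSERTION_RULE_RE, fired)))
    return(res("well_annotated", "exception_insertion"))

  definite <- assignments$category[assignments$category != "insufficient"]
  if (length(definite) == 0)
    return(res("yome", "agreement", low = TRUE))
  if (length(unique(definite)) == 1)
    return(res(definite[1], "agreement"))
  if (!is.null(override) && !is.na(override))
    return(res(override, "manual"))
  res(NA_character_, "unresolved")
}

#' Detect genes with no information
#'
#' TRUE iff every scanned piece of content attached to the gene is empty,
#' begins with a stock no-information phrase, or is a domain/family-only
#' annotation. Genes annotated only with a protein domain remain in the
#' y-ome but are flagged here.
#'
#' @param features data.frame of all the gene's features (`feature_type`,
#'   `value`)
#' @param rules a `yome_rules` object (phrase list + scanned feature types)
#' @return logical scalar
#' @export
detect_no_info <- function(features, rules) {
  scanned <- features[features$feature_type %in% rules$no_info_feature_types, ,
                      drop = FALSE]
  if (nrow(scanned) == 0) return(TRUE)
  v <- tolower(trimws(scanned$value))
  uninformative <- !nzchar(v)
  for (p in rules$no_info_phrases) {
    uninformative <- uninformative | startsWith(v, p)
  }
  # domain/family-only rows are checked separately so a gene carrying only a
  # domain_only feature plus empty text still flags
  all(uninformative)
}

#' Consensus over a whole categorization table
#'
#' Applies [apply_consensus()] to every gene, attaches the no-information
#' flag (only y-ome genes are flagged), and carries genes with no
#' categorizable features as all-insufficient (default yome, low confidence).
#'
#' @param assignments output of [categorize_store()]
#' @param store the `feature_store` (for no-info detection and names)
#' @param rules a `yome_rules` object
#' @param overrides optional manual-override data.frame
#'   (gene_id, category, justification, curator, date)
#' @return data.frame: gene_id, primary_name, category (NA while
#'   unresolved), basis, no_info, low_confidence, fired_rules
#' @export
consensus_table <- function(assignments, store, rules = load_rules(),
                            overrides = NULL) {
  if (!is.null(overrides)) validate_overrides(overrides)
  ov_map <- if (is.null(overrides) || nrow(overrides) == 0) character(0) else
    stats::setNames(overrides$category, overrides$gene_id)
  reg <- store$genes
  by_gene <- split(assignments, assignments$gene_id)
  feats_by_gene <- split(store$features, store$features$gene_id)

  n <- nrow(reg)
  category <- character(n); basis <- character(n)
  low <- logical(n); no_info <- logical(n); fired <- character(n)
  for (i in seq_len(n)) {
    gid <- reg$gene_id[i]
    a <- by_gene[[gid]]
    if (is.null(a)) {
      a <- data.frame(kb = "none", category = "insufficient", fired_rules = "",
                      stringsAsFactors = FALSE)
    }
    r <- apply_consensus(a, override = unname(ov_map[gid]))
    category[i] <- r$category
    basis[i] <- r$basis
    low[i] <- r$low_confidence
    fired[i] <- paste(a$fired_rules[nzchar(a$fired_rules)], collapse = ";")
    f <- feats_by_gene[[gid]]
    ni <- if (is.null(f)) TRUE else detect_no_info(f, rules)
    no_info[i] <- ni && identical(r$category, "yome")
  }
  data.frame(gene_id = reg$gene_id, primary_name = reg$primary_name,
             category = category, basis = basis, no_info = no_info,
             low_confidence = low, fired_rules = fired,
             stringsAsFactors = FALSE)
}

validate_overrides <- function(overrides) {
  need <- c("gene_id", "category")
  stopifnot(all(need %in% names(overrides)))
  if (!all(overrides$category %in% final_categories())) {
    stop("override categories must be yome / well_annotated / excluded", call. = FALSE)
  }
  if ("justification" %in% names(overrides) &&
      any(!nzchar(trimws(overrides$justification)))) {
    stop("every manual override needs a non-empty justification", call. = FALSE)
  }
  invisible(overrides)
}

#' Finalize the category table
#'
#' Applies manual overrides (an override always wins, with a warning when
#' the gene was not actually unresolved) and resolves remaining unresolved
#' genes: in strict mode they are an error naming the genes; in permissive
#' mode they default to yome and keep basis "unresolved" as a visible flag.
#' The result is a full partition: every gene has exactly one of
#' yome / well_annotated / excluded.
#'
#' @param records output of [consensus_table()]
#' @param overrides optional manual-override data.frame
#' @param strict fail on uncovered unresolved genes (default TRUE)
#' @return the finalized data.frame; counts by category and basis are
#'   attached as attribute `counts`
#' @export
finalize <- function(records, overrides = NULL, strict = TRUE) {
  out <- records
  if (!is.null(overrides) && nrow(overrides) > 0) {
    validate_overrides(overrides)
    for (i in seq_len(nrow(overrides))) {
      gid <- overrides$gene_id[i]
      j <- which(out$gene_id == gid)
      if (length(j) == 0) next
      if (out$basis[j] != "unresolved" && out$basis[j] != "manual") {
        warning(sprintf("override on gene %s which was not unresolved (basis=%s); override wins",
                        gid, out$basis[j]), call. = FALSE)
      }
      out$category[j] <- overrides$category[i]
      out$basis[j] <- "manual"
      out$no_info[j] <- out$no_info[j] && overrides$category[i] == "yome"
    }
  }
  open <- which(out$basis == "unresolved")
  if (length(open) > 0) {
    if (strict) {
      stop(sprintf("unresolved genes without manual override: %s",
                   paste(out$gene_id[open], collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("%d unresolved gene(s) pass through as yome (permissive mode)",
                    length(open)), call. = FALSE)
    out$category[open] <- "yome"
  }
  stopifnot(all(out$category %in% final_categories()))
  attr(out, "counts") <- list(
    by_category = table(factor(out$category, levels = final_categories())),
    by_basis = table(out$basis),
    no_info = sum(out$no_info)
  )
  out
}
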