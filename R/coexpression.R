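# Co-expression module composition: summarize externally produced
# gene -> module assignments by final category, and rank y-ome candidates.

#' Summarize co-expression modules by category
#'
#' Counts module members per final category, overall totals, and how many
#' registry genes were never assigned to a module. A gene may appear in at
#' most one module; duplicates are a validation error, as are assigned
#' genes missing from the category table.
#'
#' @param assignments data.frame with gene_id, module_id (the output table
#'   of an external weighted-correlation module detector)
#' @param categories finalized category table (gene_id, category)
#' @return list with `per_module` (module_id, well_annotated, yome,
#'   excluded, size), `totals`, `n_modules`, `n_assigned`, `n_unassigned`
#' @export
summarize_modules <- function(assignments, categories) {
  stopifnot(all(c("gene_id", "module_id") %in% names(assignments)))
  dup <- unique(assignments$gene_id[duplicated(assignments$gene_id)])
  if (length(dup) > 0) {
    stop(sprintf("gene(s) assigned to more than one module: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(assignments$gene_id, categories$gene_id)
  if (length(unknown) > 0) {
    stop(sprintf("module assignment references unknown gene(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (nrow(assignments) == 0) {
    return(list(per_module = data.frame(module_id = character(),
                                        well_annotated = integer(),
                                        yome = integer(), excluded = integer(),
                                        size = integer()),
                totals = stats::setNames(rep(0L, 3), final_categories()),
                n_modules = 0L, n_assigned = 0L,
                n_unassigned = nrow(categories)))
  }
  cat_map <- stats::setNames(categories$category, categories$gene_id)
  m <- data.frame(module_id = assignments$module_id,
                  category = factor(cat_map[assignments$gene_id],
                                    levels = final_categories()))
  tab <- as.data.frame.matrix(table(m$module_id, m$category))
  per_module <- data.frame(module_id = rownames(tab), tab,
                           size = rowSums(tab), row.names = NULL,
                           stringsAsFactors = FALSE)
  per_module <- per_module[, c("module_id", "well_annotated", "yome",
                               "excluded", "size")]
  totals <- colSums(tab)
  list(per_module = per_module,
       totals = stats::setNames(as.integer(totals), names(totals)),
       n_modules = nrow(per_module),
       n_assigned = nrow(assignments),
       n_unassigned = sum(!categories$gene_id %in% assignments$gene_id))
}

#' Rank y-ome candidate genes by module company
#'
#' y-ome genes that share a module with well-annotated genes are the
#' natural priority targets for experimental characterization: their
#' co-members hint at function. Candidates are ordered by the fraction of
#' well-annotated genes among their co-members (descending), then module
#' size (descending), then gene_id (deterministic tie-break).
#'
#' @param assignments gene -> module table (validated as in
#'   [summarize_modules()])
#' @param categories finalized category table
#' @return data.frame: rank, gene_id, module_id, well_fraction, module_size
#' @export
rank_candidate_genes <- function(assignments, categories) {
  summ <- summarize_modules(assignments, categories)  # validates inputs
  pm <- summ$per_module
  cat_map <- stats::setNames(categories$category, categories$gene_id)
  cand <- assignments[cat_map[assignments$gene_id] == "yome", , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(rank = integer(), gene_id = character(),
                      module_id = character(), well_fraction = numeric(),
                      module_size = integer()))
  }
  size_map <- stats::setNames(pm$size, pm$module_id)
  well_map <- stats::setNames(pm$well_annotated, pm$module_id)
  msize <- size_map[cand$module_id]
  comembers <- pmax(msize - 1L, 1L)
  cand$well_fraction <- unname(well_map[cand$module_id] / comembers)
  cand$module_size <- unname(as.integer(msize))
  ord <- order(-cand$well_fraction, -cand$module_size, cand$gene_id)
  cand <- cand[ord, c("gene_id", "module_id", "well_fraction", "module_size")]
  data.frame(rank = seq_len(nrow(cand)), cand, row.names = NULL,
             stringsAsFactors = FALSE)
}
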