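# Naming-convention cross-tabulation and external gene-set comparison.

#' Cross-tabulate 'y'-prefixed primary names against final category
#'
#' The historical naming convention gives unannotated reading frames
#' primary names starting with 'y'; name and annotation status have
#' drifted apart, which this 2 x 3 table quantifies. The prefix test is
#' case-insensitive and uses the registry primary name (not synonyms).
#'
#' @param categories finalized category table with primary_name
#' @return 2 x 3 integer matrix, rows `y_prefix` / `other`, columns the
#'   final categories
#' @export
yname_crosstab <- function(categories) {
  yprefix <- factor(ifelse(grepl("^y", categories$primary_name, ignore.case = TRUE),
                           "y_prefix", "other"),
                    levels = c("y_prefix", "other"))
  cat <- factor(categories$category, levels = final_categories())
  tab <- table(yprefix, cat)
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Compare the category table with an external gene list
#'
#' Counts how many genes of an external list (e.g. the gene set of a
#' genome-scale model) fall in each final category; list entries are
#' matched by gene_id first, then by primary name, and anything unmatched
#' is reported rather than dropped silently.
#'
#' @param categories finalized category table
#' @param external_genes character vector of gene identifiers (non-empty)
#' @return list with `counts` (named by category), `matched`
#'   (data.frame external_id, gene_id, category), `unmatched`
#' @export
compare_gene_set <- function(categories, external_genes) {
  if (length(external_genes) == 0) {
    stop("external gene list is empty", call. = FALSE)
  }
  external_genes <- unique(trimws(external_genes))
  external_genes <- external_genes[nzchar(external_genes)]
  id_map <- stats::setNames(categories$gene_id, categories$gene_id)
  name_map <- stats::setNames(categories$gene_id, categories$primary_name)
  gid <- unname(id_map[external_genes])
  gid[is.na(gid)] <- unname(name_map[external_genes[is.na(gid)]])
  matched <- !is.na(gid)
  cat_map <- stats::setNames(categories$category, categories$gene_id)
  counts <- table(factor(cat_map[gid[matched]], levels = final_categories()))
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    matched = data.frame(external_id = external_genes[matched],
                         gene_id = gid[matched],
                         category = unname(cat_map[gid[matched]]),
                         stringsAsFactors = FALSE),
    unmatched = external_genes[!matched]
  )
}
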