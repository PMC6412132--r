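# End-to-end orchestration: ingest -> categorize -> consensus -> analyses,
# plus the summary statistics block.

#' Summarize a finalized category table
#'
#' Counts and percentages per final category, the basis breakdown, and the
#' no-information count. Percentages are 100 * count / total rounded
#' half-up to one decimal (so a 1600-of-4623 y-ome reads 34.6); note that
#' half-up rounding is a documented convention and other roundings of the
#' same counts can differ in the last digit.
#'
#' @param categories finalized category table (from [finalize()]), or a
#'   named vector of counts over the final categories
#' @return list with `total`, `counts`, `percentages`, `basis_counts`,
#'   `no_info_count`
#' @export
summarize_categories <- function(categories) {
  if (is.numeric(categories)) {
    counts <- categories
    stopifnot(all(names(counts) %in% final_categories()))
    basis_counts <- integer(0)
    no_info <- NA_integer_
  } else {
    counts <- table(factor(categories$category, levels = final_categories()))
    counts <- stats::setNames(as.integer(counts), names(counts))
    basis_counts <- table(categories$basis)
    basis_counts <- stats::setNames(as.integer(basis_counts), names(basis_counts))
    no_info <- sum(categories$no_info)
  }
  total <- sum(counts)
  perc <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * 0
  list(total = as.integer(total),
       counts = counts,
       percentages = perc,
       basis_counts = basis_counts,
       no_info_count = no_info)
}

read_overrides <- function(path) {
  ov <- read_tsv_chr(path)
  if (nrow(ov) > 0) validate_overrides(ov)
  ov
}

read_counts_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

read_lengths <- function(path) {
  df <- read_tsv_chr(path)
  stats::setNames(as.numeric(df$length), df$gene_id)
}

#' Run the whole y-ome determination pipeline
#'
#' Stages run in order ingest -> categorize -> consensus -> analyses, and
#' every stage's table is written under `out_dir`. Inputs are either real
#' files (named in `inputs`) or generated from a [synthetic_spec()]; the
#' synthetic route writes its inputs to `out_dir/inputs` first and then
#' ingests those files, so the file contracts are exercised end to end.
#'
#' @param inputs named list of paths: knowledge-base tables (`ecocyc`,
#'   `ecogene`, `uniprot`, `regulondb`), and optionally `overrides`,
#'   `counts`, `lengths`, `samples`, `positions` (or `annotation`),
#'   `modules`, `external_genes`
#' @param synthetic a [synthetic_spec()]; mutually exclusive with `inputs`
#' @param out_dir output directory
#' @param rules rule-set path (NULL = packaged default)
#' @param word_sets word-set path (NULL = packaged default)
#' @param strict fail on unresolved genes without overrides (default TRUE)
#' @param r2_threshold replicate QC threshold
#' @param top_percentile size of the "top expression" slice (default 20)
#' @param kappa von Mises KDE concentration
#' @param genome_length chromosome length for position angles (defaults to
#'   the synthetic spec's, else the reference chromosome)
#' @return invisibly, a list with `categories`, `summary`, and per-analysis
#'   results; files land in `out_dir` (`categories.tsv`, `summary.json`,
#'   analysis TSVs, `pipeline.log`)
#' @export
run_pipeline <- function(inputs = NULL, synthetic = NULL, out_dir,
                         rules = NULL, word_sets = NULL, strict = TRUE,
                         r2_threshold = 0.9, top_percentile = 20,
                         kappa = 50, genome_length = NULL) {
  if (is.null(inputs) == is.null(synthetic)) {
    stop("provide exactly one of `inputs` or `synthetic`", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    writeLines(log_lines, log_path)
  }

  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_spec"))
    say("generating synthetic inputs (n_genes=%d, seed=%d)",
        synthetic$n_genes, synthetic$seed)
    inputs <- generate_synthetic_inputs(synthetic, file.path(out_dir, "inputs"))
    if (is.null(genome_length)) genome_length <- synthetic$genome_length
  }
  genome_length <- genome_length %||% ecoli_genome_length()

  kb_paths <- inputs[intersect(c("ecocyc", "ecogene", "uniprot", "regulondb",
                                 "refseq"), names(inputs))]
  if (length(kb_paths) == 0) stop("no knowledge-base tables in `inputs`", call. = FALSE)
  for (nm in names(inputs)) {
    p <- inputs[[nm]]
    if (nm != "labels" && is.character(p)) stop_missing_file(p, nm)
  }

  rules_obj <- load_rules(rules)
  say("ingesting %d knowledge-base tables", length(kb_paths))
  store <- ingest_kb_tables(kb_paths)
  say("registry: %d unique genes, %d features",
      nrow(store$genes), nrow(store$features))

  assignments <- categorize_store(store, rules_obj)
  say("categorized %d gene x source pairs", nrow(assignments))

  overrides <- if (!is.null(inputs$overrides)) read_overrides(inputs$overrides)
  records <- consensus_table(assignments, store, rules_obj, overrides = overrides)
  final <- finalize(records, overrides = overrides, strict = strict)
  write_tsv(final, file.path(out_dir, "categories.tsv"))
  summary <- summarize_categories(final)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("final partition: %s",
      paste(sprintf("%s=%d", names(summary$counts), summary$counts), collapse = " "))

  results <- list(store = store, assignments = assignments,
                  categories = final, summary = summary)

  if (!is.null(inputs$counts)) {
    counts <- read_counts_matrix(inputs$counts)
    glengths <- read_lengths(inputs$lengths)
    samples <- read_tsv_chr(inputs$samples)
    lt <- log_tpm(tpm_from_counts(counts, glengths))
    qc <- replicate_qc(lt, samples, r2_threshold = r2_threshold)
    means <- mean_expression(qc$log_tpm, qc$samples)
    contrast <- compare_categories(means, final)
    top <- percentile_threshold(means, q = top_percentile)
    expr_tbl <- data.frame(gene_id = names(means), mean_log_tpm = unname(means),
                           stringsAsFactors = FALSE)
    write_tsv(expr_tbl, file.path(out_dir, "mean_expression.tsv"))
    write_tsv(qc$report, file.path(out_dir, "replicate_qc.tsv"))
    say("expression: t=%.2f p=%.3g; top-%d%% threshold %.3f",
        contrast$statistic, contrast$p_value, top_percentile, top$threshold)
    results$expression <- list(qc = qc$report, means = means,
                               contrast = contrast, top = top)
  }

  if (!is.null(inputs$positions) || !is.null(inputs$annotation)) {
    pos <- if (!is.null(inputs$positions)) {
      df <- read_tsv_chr(inputs$positions)
      df$start <- as.integer(df$start)
      df
    } else {
      load_positions(inputs$annotation, store$genes)$positions
    }
    ang <- to_angles(pos, genome_length)
    cat_map <- stats::setNames(final$category, final$gene_id)
    angle_sets <- split(ang$angle, cat_map[ang$gene_id])
    dens <- lapply(angle_sets[lengths(angle_sets) > 0], vonmises_kde,
                   kappa = kappa)
    dens_tbl <- do.call(rbind, lapply(names(dens), function(cat) {
      data.frame(category = cat, angle = dens[[cat]]$grid,
                 density = dens[[cat]]$density, stringsAsFactors = FALSE)
    }))
    write_tsv(dens_tbl, file.path(out_dir, "chromosome_density.tsv"))
    enrich <- region_enrichment(angle_sets)
    write_tsv(enrich, file.path(out_dir, "chromosome_enrichment.tsv"))
    say("chromosome: %s", paste(sprintf("%s ter/ori=%.2f", enrich$category,
                                        enrich$ratio), collapse = " "))
    results$chromosome <- list(densities = dens, enrichment = enrich)
  }

  if (!is.null(inputs$modules)) {
    mods <- read_tsv_chr(inputs$modules)
    summ <- summarize_modules(mods, final)
    ranked <- rank_candidate_genes(mods, final)
    write_tsv(summ$per_module, file.path(out_dir, "module_summary.tsv"))
    write_tsv(ranked, file.path(out_dir, "candidate_genes.tsv"))
    say("modules: %d modules, %d genes assigned", summ$n_modules, summ$n_assigned)
    results$modules <- list(summary = summ, candidates = ranked)
  }

  ws <- load_word_sets(word_sets)
  tf <- count_word_sets(store$features, final, ws)
  write_tsv(tf, file.path(out_dir, "term_frequency.tsv"))
  results$term_frequency <- tf

  xt <- yname_crosstab(final)
  write_tsv(data.frame(name_prefix = rownames(xt), xt, check.names = FALSE),
            file.path(out_dir, "yname_crosstab.tsv"))
  results$yname_crosstab <- xt

  if (!is.null(inputs$external_genes)) {
    ext <- readLines(inputs$external_genes)
    cmp <- compare_gene_set(final, ext)
    write_tsv(cmp$matched, file.path(out_dir, "gene_set_overlap.tsv"))
    results$gene_set <- cmp
  }

  say("pipeline complete")
  invisible(results)
}
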