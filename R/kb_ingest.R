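# Knowledge-base ingest: canonical feature tables -> feature store + gene
# registry resolved across sources.

canonical_columns <- function() {
  c("kb", "locus_tag", "primary_name", "synonyms", "feature_type", "feature_value")
}

#' Parse a canonical knowledge-base feature table
#'
#' The pipeline's ingest contract is a UTF-8 TSV with columns
#' `kb, locus_tag, primary_name, synonyms, feature_type, feature_value`
#' (synonyms pipe-separated, possibly empty). One data row becomes one
#' feature. Values are preserved verbatim; no case folding happens at ingest.
#'
#' Malformed rows (unknown feature type, no gene identifier at all,
#' non-integer or out-of-range annotation score) are collected with their
#' line numbers and skipped, never fatal. A missing required column is a
#' schema error and is fatal.
#'
#' @param path path to the TSV
#' @param kb optional knowledge-base name; when given, rows must carry this
#'   kb (or an empty kb column, which is filled in)
#' @return list with `features` (well-formed rows) and `errors`
#'   (data.frame of line, message)
#' @export
parse_feature_table <- function(path, kb = NULL) {
  stop_missing_file(path, "feature table")
  df <- read_tsv_chr(path)
  missing_cols <- setdiff(canonical_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[canonical_columns()]
  if (!is.null(kb)) {
    kb <- match.arg(kb, yome_kbs())
    blank <- !nzchar(df$kb)
    df$kb[blank] <- kb
    if (any(df$kb != kb)) {
      stop(sprintf("feature table %s contains rows for kb other than '%s'", path, kb),
           call. = FALSE)
    }
  }
  n <- nrow(df)
  line <- seq_len(n) + 1L  # header is line 1
  errs <- character(n)
  errs[!df$kb %in% yome_kbs()] <- "unknown knowledge base"
  errs[!df$feature_type %in% yome_feature_types() & !nzchar(errs)] <-
    "unknown feature_type"
  no_id <- !nzchar(trimws(df$locus_tag)) & !nzchar(trimws(df$primary_name))
  errs[no_id & !nzchar(errs)] <- "row has neither locus_tag nor primary_name"
  is_score <- df$feature_type == "annotation_score"
  bad_score <- is_score & !grepl("^[1-5]$", trimws(df$feature_value))
  errs[bad_score & !nzchar(errs)] <- "annotation_score must be an integer 1-5"
  bad <- nzchar(errs)
  list(
    features = df[!bad, , drop = FALSE],
    errors = data.frame(line = line[bad], message = errs[bad],
                        stringsAsFactors = FALSE)
  )
}

# Per-KB gene fragments (one row per distinct kb/locus/name/synonyms combo)
fragments_from_features <- function(features) {
  unique(features[, c("kb", "locus_tag", "primary_name", "synonyms")])
}

#' Build the unique-gene registry across knowledge bases
#'
#' Fragments sharing a locus tag merge into one gene; fragments without a
#' locus tag merge by exact primary-name or synonym match; everything else
#' becomes its own gene with a generated surrogate identifier. Identity
#' precedence is locus tag > exact primary-name match > synonym match —
#' locus tags are the only stable cross-source key.
#'
#' When fragments with the same locus tag carry conflicting primary names,
#' the locus tag wins as identifier, the name from the highest-precedence
#' source (ecocyc > ecogene > uniprot > regulondb > refseq) becomes primary
#' and the others become synonyms; the decision is recorded in the merge log.
#'
#' @param fragments data.frame with columns kb, locus_tag, primary_name,
#'   synonyms (pipe-separated), e.g. from [parse_feature_table()]
#' @return data.frame (class `gene_registry`) with columns gene_id,
#'   primary_name, synonyms, sources; attributes `merge_log` (character)
#'   and `kb_names` (per-source primary names, used by structured rules)
#' @export
build_registry <- function(fragments) {
  stopifnot(all(c("kb", "locus_tag", "primary_name", "synonyms") %in% names(fragments)))
  frag <- unique(fragments[, c("kb", "locus_tag", "primary_name", "synonyms")])
  frag$locus_tag <- trimws(frag$locus_tag)
  frag$primary_name <- trimws(frag$primary_name)
  kb_order <- yome_kbs()
  frag <- frag[order(match(frag$kb, kb_order)), , drop = FALSE]

  merge_log <- character(0)
  genes <- list()     # gene_id -> list(primary_name, synonyms, sources)
  name_index <- new.env(parent = emptyenv())  # name -> gene_id

  register_name <- function(name, gid) {
    if (nzchar(name) && is.null(name_index[[name]])) name_index[[name]] <- gid
  }
  syn_split <- function(s) {
    s <- unlist(strsplit(s, "|", fixed = TRUE))
    s[nzchar(trimws(s))]
  }

  add_fragment <- function(gid, fr) {
    g <- genes[[gid]]
    syns <- syn_split(fr$synonyms)
    if (is.null(g)) {
      g <- list(primary_name = fr$primary_name, synonyms = syns, sources = fr$kb)
    } else {
      if (nzchar(fr$primary_name) && !nzchar(g$primary_name)) {
        g$primary_name <- fr$primary_name
      } else if (nzchar(fr$primary_name) && fr$primary_name != g$primary_name) {
        merge_log <<- c(merge_log, sprintf(
          "gene %s: conflicting primary names '%s' (%s) vs '%s'; keeping '%s', demoting other to synonym",
          gid, g$primary_name, fr$kb, fr$primary_name, g$primary_name))
        g$synonyms <- union(g$synonyms, fr$primary_name)
      }
      g$synonyms <- union(g$synonyms, syns)
      g$sources <- union(g$sources, fr$kb)
    }
    genes[[gid]] <<- g
    register_name(g$primary_name, gid)
    for (s in genes[[gid]]$synonyms) register_name(s, gid)
  }

  with_lt <- frag[nzchar(frag$locus_tag), , drop = FALSE]
  for (i in seq_len(nrow(with_lt))) {
    add_fragment(with_lt$locus_tag[i], with_lt[i, ])
  }

  surrogate <- 0L
  no_lt <- frag[!nzchar(frag$locus_tag), , drop = FALSE]
  for (i in seq_len(nrow(no_lt))) {
    fr <- no_lt[i, ]
    candidates <- c(fr$primary_name, syn_split(fr$synonyms))
    gid <- NULL
    for (nm in candidates) {
      hit <- name_index[[nm]]
      if (!is.null(hit)) { gid <- hit; break }
    }
    if (is.null(gid)) {
      surrogate <- surrogate + 1L
      gid <- sprintf("gene_%04d", surrogate)
      merge_log <- c(merge_log, sprintf(
        "fragment %s/%s has no locus tag and no name match; surrogate id %s",
        fr$kb, fr$primary_name, gid))
    } else {
      merge_log <- c(merge_log, sprintf(
        "fragment %s/%s merged into %s by name match", fr$kb, fr$primary_name, gid))
    }
    add_fragment(gid, fr)
  }

  ids <- names(genes)
  reg <- data.frame(
    gene_id = ids,
    primary_name = vapply(genes, function(g) g$primary_name, ""),
    synonyms = vapply(genes, function(g)
      paste(setdiff(g$synonyms, g$primary_name), collapse = "|"), ""),
    sources = vapply(genes, function(g)
      paste(intersect(kb_order, g$sources), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  reg <- reg[order(reg$gene_id), , drop = FALSE]
  rownames(reg) <- NULL

  # per-source primary names (needed by structured rules, e.g. the
  # apostrophe pseudogene convention that only holds in one source)
  kb_names <- frag[nzchar(frag$primary_name), c("kb", "locus_tag", "primary_name")]
  kb_names$gene_id <- ifelse(nzchar(kb_names$locus_tag), kb_names$locus_tag, NA_character_)
  for (i in which(is.na(kb_names$gene_id))) {
    kb_names$gene_id[i] <- name_index[[kb_names$primary_name[i]]] %||% NA_character_
  }
  kb_names <- unique(kb_names[!is.na(kb_names$gene_id),
                              c("gene_id", "kb", "primary_name")])
  rownames(kb_names) <- NULL

  structure(reg, class = c("gene_registry", "data.frame"),
            merge_log = merge_log, kb_names = kb_names)
}

# Map feature rows to registry gene ids (locus tag first, then names).
resolve_gene_ids <- function(features, registry) {
  kb_names <- attr(registry, "kb_names")
  name_map <- c(
    stats::setNames(registry$gene_id, registry$primary_name),
    stats::setNames(kb_names$gene_id, kb_names$primary_name)
  )
  gid <- ifelse(nzchar(trimws(features$locus_tag)),
                trimws(features$locus_tag),
                unname(name_map[trimws(features$primary_name)]))
  # synonym fallback for names not seen as any primary name
  still <- which(is.na(gid))
  if (length(still) > 0) {
    syn_pairs <- do.call(rbind, lapply(seq_len(nrow(registry)), function(i) {
      syns <- unlist(strsplit(registry$synonyms[i], "|", fixed = TRUE))
      syns <- syns[nzchar(syns)]
      if (length(syns) == 0) return(NULL)
      data.frame(name = syns, gene_id = registry$gene_id[i], stringsAsFactors = FALSE)
    }))
    if (!is.null(syn_pairs)) {
      syn_map <- stats::setNames(syn_pairs$gene_id, syn_pairs$name)
      gid[still] <- unname(syn_map[trimws(features$primary_name[still])])
    }
  }
  gid
}

#' Ingest knowledge-base feature tables into a feature store
#'
#' Parses each table, builds the cross-source gene registry and resolves
#' every feature to a registry gene. The result is the `feature_store`
#' consumed by categorization and the downstream analyses.
#'
#' @param paths named character vector or list, names are knowledge-base
#'   names (ecocyc, ecogene, uniprot, regulondb, refseq), values file paths
#' @param versions optional named character vector of source version strings
#' @return list of class `feature_store` with elements `genes`
#'   (the registry), `features` (gene_id, kb, feature_type, value),
#'   `provenance`, and `ingest_errors`
#' @export
ingest_kb_tables <- function(paths, versions = NULL) {
  stopifnot(length(paths) > 0, !is.null(names(paths)))
  parsed <- lapply(names(paths), function(kb) parse_feature_table(paths[[kb]], kb = kb))
  names(parsed) <- names(paths)
  all_feats <- do.call(rbind, lapply(parsed, `[[`, "features"))
  registry <- build_registry(fragments_from_features(all_feats))
  gene_id <- resolve_gene_ids(all_feats, registry)
  features <- data.frame(
    gene_id = gene_id,
    kb = all_feats$kb,
    feature_type = all_feats$feature_type,
    value = all_feats$feature_value,
    stringsAsFactors = FALSE
  )
  features <- features[!is.na(features$gene_id), , drop = FALSE]
  rownames(features) <- NULL
  errors <- do.call(rbind, lapply(names(parsed), function(kb) {
    e <- parsed[[kb]]$errors
    if (nrow(e) == 0) return(NULL)
    cbind(kb = kb, e, stringsAsFactors = FALSE)
  }))
  prov <- data.frame(
    kb = names(paths),
    path = unname(vapply(paths, as.character, "")),
    version = if (is.null(versions)) "" else unname(versions[names(paths)]),
    stringsAsFactors = FALSE
  )
  structure(
    list(genes = registry, features = features, provenance = prov,
         ingest_errors = errors %||% data.frame()),
    class = "feature_store"
  )
}

#' Serialize / reload a feature store
#'
#' The store persists as a directory of plain TSV tables (`genes.tsv`,
#' `features.tsv`, `kb_names.tsv`, `provenance.tsv`) so that a store can be
#' written, inspected and reloaded losslessly.
#'
#' @param store a `feature_store`
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly (write) / the reloaded store (read)
#' @export
write_feature_store <- function(store, dir) {
  stopifnot(inherits(store, "feature_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(store$genes), file.path(dir, "genes.tsv"))
  write_tsv(store$features, file.path(dir, "features.tsv"))
  write_tsv(attr(store$genes, "kb_names"), file.path(dir, "kb_names.tsv"))
  write_tsv(store$provenance, file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  genes <- read_tsv_chr(file.path(dir, "genes.tsv"))
  kb_names <- read_tsv_chr(file.path(dir, "kb_names.tsv"))
  genes <- structure(genes, class = c("gene_registry", "data.frame"),
                     merge_log = character(0), kb_names = kb_names)
  feats <- read_tsv_chr(file.path(dir, "features.tsv"))
  names(feats) <- c("gene_id", "kb", "feature_type", "value")
  structure(
    list(genes = genes, features = feats,
         provenance = read_tsv_chr(file.path(dir, "provenance.tsv")),
         ingest_errors = data.frame()),
    class = "feature_store"
  )
}

# Genome annotation ------------------------------------------------------------

#' Extract gene start positions from a genome annotation
#'
#' Reads gene features from a GFF3 file (via rtracklayer) or a GenBank flat
#' file (internal reader) and matches them to the registry by locus tag,
#' then by name. Coordinates are 1-based on the forward-numbered circular
#' chromosome; the reported start is the biological start site (left end on
#' the plus strand, right end on the minus strand). Strand is recorded but
#' not otherwise used.
#'
#' @param path annotation file (GFF3 or GenBank flat file)
#' @param registry a `gene_registry`
#' @param format "auto" (by content), "gff3" or "genbank"
#' @return list with `positions` (gene_id, start, strand), `genome_length`,
#'   and `gaps` (registry genes absent from the annotation)
#' @export
load_positions <- function(path, registry, format = c("auto", "gff3", "genbank")) {
  format <- match.arg(format)
  stop_missing_file(path, "genome annotation")
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "gff3"
  }
  ann <- if (format == "gff3") read_gff3_genes(path) else read_genbank_genes(path)
  if (is.na(ann$genome_length)) {
    stop("annotation has no sequence length (##sequence-region pragma or LOCUS line required)",
         call. = FALSE)
  }
  bad <- ann$genes$start < 1 | ann$genes$start > ann$genome_length
  if (any(bad)) {
    stop(sprintf("gene start outside [1, %d] for: %s", ann$genome_length,
                 paste(utils::head(ann$genes$id[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  # match: locus tag (gene_id), then primary name
  name_map <- stats::setNames(registry$gene_id, registry$primary_name)
  gid <- ifelse(ann$genes$locus_tag %in% registry$gene_id, ann$genes$locus_tag,
                unname(name_map[ann$genes$name]))
  matched <- !is.na(gid)
  if (!any(matched)) {
    stop("no annotation gene matched the registry (identifier namespace mismatch?)",
         call. = FALSE)
  }
  positions <- data.frame(
    gene_id = gid[matched],
    start = ann$genes$start[matched],
    strand = ann$genes$strand[matched],
    stringsAsFactors = FALSE
  )
  positions <- positions[!duplicated(positions$gene_id), , drop = FALSE]
  rownames(positions) <- NULL
  list(positions = positions,
       genome_length = ann$genome_length,
       gaps = setdiff(registry$gene_id, positions$gene_id))
}

read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  glen <- NA_integer_
  pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(pragma) > 0) {
    glen <- as.integer(strsplit(trimws(pragma[1]), "\\s+")[[1]][4])
  }
  gr <- gr[gr$type == "gene"]
  md <- as.data.frame(gr)
  lt <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag) else rep(NA, nrow(md))
  nm <- if ("Name" %in% names(md)) as.character(md$Name)
        else if ("gene" %in% names(md)) as.character(md$gene) else rep(NA, nrow(md))
  start <- ifelse(md$strand == "-", md$end, md$start)
  list(genes = data.frame(id = ifelse(is.na(lt), nm, lt),
                          locus_tag = ifelse(is.na(lt), "", lt),
                          name = ifelse(is.na(nm), "", nm),
                          start = as.integer(start),
                          strand = as.character(md$strand),
                          stringsAsFactors = FALSE),
       genome_length = glen)
}

# Minimal GenBank flat-file reader: LOCUS length plus `gene` features with
# locus_tag / gene qualifiers. Handles plain and complement() locations.
read_genbank_genes <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  glen <- if (length(locus) > 0) {
    as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1]))
  } else NA_integer_
  gene_idx <- grep("^\\s{5}gene\\s", lines)
  genes <- lapply(gene_idx, function(i) {
    loc <- trimws(sub("^\\s{5}gene\\s+", "", lines[i]))
    comp <- grepl("^complement", loc)
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 1) return(NULL)
    start <- if (comp) max(nums) else min(nums)
    # qualifiers until the next feature key (a non-qualifier line)
    j <- i + 1L
    lt <- ""; nm <- ""
    while (j <= length(lines) && grepl("^\\s{21}", lines[j])) {
      q <- trimws(lines[j])
      if (grepl("^/locus_tag=", q)) lt <- gsub('^/locus_tag="|"$', "", q)
      if (grepl("^/gene=", q)) nm <- gsub('^/gene="|"$', "", q)
      j <- j + 1L
    }
    data.frame(id = if (nzchar(lt)) lt else nm, locus_tag = lt, name = nm,
               start = start, strand = if (comp) "-" else "+",
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, genes)
  if (is.null(genes)) genes <- data.frame(id = character(), locus_tag = character(),
                                          name = character(), start = integer(),
                                          strand = character())
  list(genes = genes, genome_length = glen)
}
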