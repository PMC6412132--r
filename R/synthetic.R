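# Synthetic knowledge-base suites, expression matrices, chromosome
# positions and module assignments with planted ground truth, so every
# pipeline stage is testable without external downloads.

#' Specification for a synthetic study
#'
#' Defaults mirror the documented study conditions: category fractions are
#' the reported proportions of a ~4600-gene bacterial registry (y-ome
#' 1600/4623, well-annotated 2803/4623, excluded 220/4623), the
#' no-information rate the reported 111 of 1600 y-ome genes, the planted
#' expression effect is a 2 log2-unit deficit for the y-ome against a
#' well-annotated mean of 6 log2 units with unit between-gene spread, and
#' y-ome gene starts concentrate toward the replication terminus with von
#' Mises concentration 2. Replicate noise defaults to 0.25 log2 units
#' (replicate R-squared around 0.97, typical of biological replicates).
#'
#' @param n_genes number of genes (>= 10)
#' @param category_fractions named fractions (yome, well_annotated,
#'   excluded) summing to 1
#' @param conflict_rate fraction of (non-excluded) genes given
#'   contradictory definite votes plus a generated manual override
#' @param no_info_rate fraction of y-ome genes given only no-information
#'   content
#' @param n_conditions,replicates expression design
#' @param delta planted y-ome expression deficit, log2 units
#' @param sigma replicate-level noise, log2 units
#' @param mu_well well-annotated mean log2 expression
#' @param position_bias von Mises concentration of y-ome starts toward the
#'   terminus (0 = uniform)
#' @param n_modules,mixing module generator: module count and probability
#'   that a member is drawn from outside the module's base category
#' @param genome_length circular chromosome length in bp
#' @param seed integer seed; all generators are deterministic given it
#' @return validated list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_genes = 1000,
                           category_fractions = c(yome = 1600, well_annotated = 2803,
                                                  excluded = 220) / 4623,
                           conflict_rate = 0,
                           no_info_rate = 111 / 1600,
                           n_conditions = 10,
                           replicates = 2,
                           delta = 2,
                           sigma = 0.25,
                           mu_well = 6,
                           position_bias = 2,
                           n_modules = 8,
                           mixing = 0.3,
                           genome_length = ecoli_genome_length(),
                           seed = 1) {
  stopifnot(n_genes >= 10,
            all(category_fractions >= 0), all(category_fractions <= 1),
            abs(sum(category_fractions) - 1) < 1e-9,
            setequal(names(category_fractions), final_categories()),
            conflict_rate >= 0, conflict_rate <= 1,
            no_info_rate >= 0, no_info_rate <= 1,
            n_conditions >= 1, replicates >= 1, sigma >= 0,
            position_bias >= 0, genome_length > n_genes)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Largest-remainder apportionment: exact planted counts at any n.
largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

base26 <- function(i, width = 3) {
  vapply(i - 1L, function(x) {
    out <- character(width)
    for (k in width:1) { out[k] <- letters[x %% 26L + 1L]; x <- x %/% 26L }
    paste(out, collapse = "")
  }, "")
}

#' Generate four knowledge-base feature tables with planted categories
#'
#' Every gene receives features that let the rule engine recover its
#' planted category: well-annotated genes get assay-grade evidence, a high
#' annotation score, a reaction equation, experimentally supported
#' transcription-factor evidence, or an insertion-element flag; y-ome genes
#' get low-annotation keyword descriptions or low annotation scores (a
#' `no_info_rate` fraction only stock no-information content); excluded
#' genes get apostrophe-suffixed names in the ecogene dump or
#' pseudogene/phantom flags. Conflicted genes instead get contradictory
#' definite votes (a low-annotation description against a high annotation
#' score) plus a manual-override entry carrying the truth, so consensus
#' must route them through the curation layer.
#'
#' @param spec a [synthetic_spec()]
#' @param dir optional output directory; when given, writes
#'   `ecocyc.tsv` ... `regulondb.tsv`, `labels.tsv`, `overrides.tsv` and
#'   `manifest.json`
#' @return list with `tables` (named list of canonical feature tables),
#'   `labels` (gene_id, primary_name, category, no_info, conflict,
#'   mechanism), `overrides`
#' @export
generate_kb_suite <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  counts <- largest_remainder(n, spec$category_fractions[final_categories()])
  category <- sample(rep(final_categories(), counts))
  width <- max(3, ceiling(log(n + 1) / log(26)))
  id_width <- max(4, nchar(as.character(n)))
  gene_id <- sprintf(paste0("b%0", id_width, "d"), seq_len(n))
  base <- base26(seq_len(n), width)

  # mechanisms by which the planted category is recoverable
  mech <- character(n)
  i_w <- which(category == "well_annotated")
  mech[i_w] <- sample(c("evidence", "score", "reaction", "dual", "regulondb",
                        "insertion"),
                      length(i_w), replace = TRUE,
                      prob = c(.30, .25, .20, .10, .10, .05))
  i_y <- which(category == "yome")
  mech[i_y] <- sample(c("keyword", "score"), length(i_y), replace = TRUE,
                      prob = c(.7, .3))
  n_noinfo <- round(length(i_y) * spec$no_info_rate)
  if (n_noinfo > 0) mech[sample(i_y, n_noinfo)] <- "no_info"
  i_x <- which(category == "excluded")
  mech[i_x] <- sample(c("apostrophe", "pseudo", "phantom"), length(i_x),
                      replace = TRUE, prob = c(.4, .4, .2))

  # conflict injection (never on the excluded track); conflicted genes
  # carry only the contradictory vote pair, so their mechanism is replaced
  conflict <- rep(FALSE, n)
  n_conf <- round(n * spec$conflict_rate)
  if (n_conf > 0) {
    pool <- which(category != "excluded")
    conflict[sample(pool, min(n_conf, length(pool)))] <- TRUE
    mech[conflict] <- "conflict"
  }

  # primary names: y-ome mostly 'y'-prefixed, well-annotated mostly not
  # (name and annotation status deliberately drift apart)
  yname <- stats::runif(n) < ifelse(category == "yome", 0.85, 0.08)
  other_prefix <- sample(setdiff(letters, c("y", "i")), n, replace = TRUE)
  primary_name <- ifelse(yname, paste0("y", base), paste0(other_prefix, base))
  primary_name[mech == "insertion"] <- paste0("ins", base[mech == "insertion"])

  yome_desc <- function(k) {
    paste(sample(c("predicted", "hypothetical", "possibly a"), k, replace = TRUE),
          sample(c("inner membrane protein", "transporter", "lipoprotein",
                   "DNA-binding protein", "enzyme", "stress protein"),
                 k, replace = TRUE))
  }
  well_desc <- function(k) {
    paste(sample(c("ATP-dependent", "membrane-bound", "periplasmic",
                   "NADH-linked", "sugar"), k, replace = TRUE),
          sample(c("transporter subunit", "oxidoreductase", "transferase",
                   "regulator of transcription", "binding protein", "enzyme"),
                 k, replace = TRUE))
  }

  rows <- vector("list", n)
  overrides <- list()
  no_info <- rep(FALSE, n)
  for (i in seq_len(n)) {
    gid <- gene_id[i]; nm <- primary_name[i]
    r <- list()
    add <- function(kb, ft, val, name = nm) {
      r[[length(r) + 1L]] <<- data.frame(
        kb = kb, locus_tag = gid, primary_name = name, synonyms = "",
        feature_type = ft, feature_value = val, stringsAsFactors = FALSE)
    }
    if (conflict[i]) {
      add("ecocyc", "description", "hypothetical protein")
      add("ecogene", "description", "")
      add("uniprot", "annotation_score", "5")
      overrides[[length(overrides) + 1L]] <- data.frame(
        gene_id = gid, category = category[i],
        justification = "synthetic curation decision for injected conflict",
        curator = "generator", date = "2026-01-01", stringsAsFactors = FALSE)
    } else {
      switch(mech[i],
        evidence = {
          add("ecocyc", "description", well_desc(1))
          add("ecocyc", "evidence",
              sample(c("assay", "traceable author statement to experimental support",
                       "reaction blocked in mutant"), 1))
          add("ecogene", "description", "")
        },
        score = {
          is_well <- category[i] == "well_annotated"
          add("ecocyc", "description",
              if (is_well) well_desc(1) else "conserved inner membrane protein")
          add("ecogene", "description", "")
          add("uniprot", "description",
              if (is_well) well_desc(1) else "conserved protein")
          add("uniprot", "annotation_score",
              as.character(if (is_well) sample(4:5, 1) else sample(1:2, 1)))
        },
        reaction = {
          add("ecocyc", "description", well_desc(1))
          add("ecocyc", "reaction_equation", "alpha + beta -> gamma")
          add("ecogene", "description", "")
        },
        dual = {
          add("ecocyc", "description", well_desc(1))
          add("ecocyc", "reaction_equation", "alpha + beta -> gamma")
          add("uniprot", "description", well_desc(1))
          add("uniprot", "annotation_score", "5")
        },
        regulondb = {
          add("ecocyc", "description", "predicted DNA-binding regulator")
          add("regulondb", "tf_evidence", "Strong")
          add("ecogene", "description", "")
        },
        insertion = {
          add("ecocyc", "description", "insertion element repeat region")
          add("ecocyc", "insertion_flag", "IS element")
          add("ecogene", "description", "")
        },
        keyword = {
          add("ecocyc", "description", yome_desc(1))
          add("ecogene", "description", "")
        },
        no_info = {
          no_info[i] <- TRUE
          add("ecocyc", "summary",
              "No information about this protein was found by an automated literature search")
          add("ecogene", "description", "")
          add("uniprot", "description", "Putative uncharacterized protein")
        },
        apostrophe = {
          add("ecocyc", "description", "")
          add("ecogene", "description", "", name = paste0(nm, "'"))
        },
        pseudo = {
          add("ecocyc", "description", "")
          add("ecocyc", "pseudogene_flag", "true")
          add("ecogene", "description", "")
        },
        phantom = {
          add("ecocyc", "description", "")
          add("ecocyc", "phantom_flag", "true")
          add("ecogene", "description", "")
        }
      )
    }
    rows[[i]] <- do.call(rbind, r)
  }
  all_rows <- do.call(rbind, rows)
  tables <- lapply(c(ecocyc = "ecocyc", ecogene = "ecogene",
                     uniprot = "uniprot", regulondb = "regulondb"),
                   function(kb) {
                     t <- all_rows[all_rows$kb == kb, , drop = FALSE]
                     rownames(t) <- NULL
                     t
                   })
  labels <- data.frame(gene_id = gene_id, primary_name = primary_name,
                       category = category, no_info = no_info,
                       conflict = conflict, mechanism = mech,
                       stringsAsFactors = FALSE)
  overrides <- if (length(overrides) > 0) do.call(rbind, overrides) else
    data.frame(gene_id = character(), category = character(),
               justification = character(), curator = character(),
               date = character(), stringsAsFactors = FALSE)
  out <- list(tables = tables, labels = labels, overrides = overrides)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (kb in names(tables)) {
      write_tsv(tables[[kb]], file.path(dir, paste0(kb, ".tsv")))
    }
    write_tsv(labels, file.path(dir, "labels.tsv"))
    write_tsv(overrides, file.path(dir, "overrides.tsv"))
    manifest <- spec
    class(manifest) <- NULL
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate a synthetic expression compendium
#'
#' Per-gene expected log2 expression is drawn Normal(mu_category, 1) with
#' the y-ome (and excluded) mean `delta` units below the well-annotated
#' mean; replicate values add Normal(0, sigma) noise, and counts are
#' rounded length-scaled log-normal values (sufficient for the
#' category-contrast statistics exercised here, not a full RNA-seq error
#' model).
#'
#' @param spec a [synthetic_spec()]
#' @param labels label table from [generate_kb_suite()]
#' @param dir optional output directory (`counts.tsv`, `lengths.tsv`,
#'   `samples.tsv`)
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_lengths` (named), `samples`, and the planted `base` expression
#' @export
generate_expression <- function(spec, labels, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- nrow(labels)
  gene_lengths <- stats::setNames(sample(300:3000, n, replace = TRUE),
                                  labels$gene_id)
  mu <- ifelse(labels$category == "well_annotated",
               spec$mu_well, spec$mu_well - spec$delta)
  base <- stats::rnorm(n, mu, 1)
  samples <- expand.grid(replicate_id = paste0("r", seq_len(spec$replicates)),
                         condition_id = sprintf("cond%02d", seq_len(spec$n_conditions)),
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample_id <- paste(samples$condition_id, samples$replicate_id, sep = "_")
  s <- nrow(samples)
  x <- matrix(base, n, s) + matrix(stats::rnorm(n * s, 0, spec$sigma), n, s)
  counts <- round(2^x * gene_lengths / 1000)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(labels$gene_id, samples$sample_id)
  out <- list(counts = counts, gene_lengths = gene_lengths,
              samples = samples, base = stats::setNames(base, labels$gene_id))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE), file.path(dir, "counts.tsv"))
    write_tsv(data.frame(gene_id = names(gene_lengths),
                         length = unname(gene_lengths)),
              file.path(dir, "lengths.tsv"))
    write_tsv(samples[, c("sample_id", "condition_id", "replicate_id")],
              file.path(dir, "samples.tsv"))
  }
  out
}

#' Generate circular gene start positions with a planted terminus bias
#'
#' y-ome gene starts are drawn from a von Mises distribution centered on
#' the terminus angle with concentration `position_bias`; all other genes
#' are uniform on the circle. Starts are distinct integers in
#' `[1, genome_length]`.
#'
#' @param spec a [synthetic_spec()]
#' @param labels label table
#' @param dir optional output directory (`positions.tsv`)
#' @return data.frame gene_id, start
#' @export
generate_positions <- function(spec, labels, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  n <- nrow(labels)
  L <- spec$genome_length
  ori <- position_to_angle(ecoli_ori_position(), ecoli_genome_length())
  ter <- (ori + pi) %% (2 * pi)
  ang <- numeric(n)
  is_y <- labels$category == "yome"
  ang[is_y] <- rvonmises(sum(is_y), ter, spec$position_bias)
  ang[!is_y] <- stats::runif(sum(!is_y), 0, 2 * pi)
  starts <- pmin(pmax(floor(ang / (2 * pi) * L) + 1, 1), L)
  dup <- duplicated(starts)
  while (any(dup)) {
    starts[dup] <- (starts[dup] %% L) + 1
    dup <- duplicated(starts)
  }
  out <- data.frame(gene_id = labels$gene_id, start = as.integer(starts),
                    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(dir, "positions.tsv"))
  }
  out
}

#' Generate gene -> co-expression-module assignments
#'
#' Builds `n_modules` modules of size >= 10. Each module has a base
#' category (mostly well-annotated); every member is drawn from the other
#' category with probability `mixing`, so `mixing = 0` yields
#' single-category modules. Each gene appears in at most one module.
#'
#' @param spec a [synthetic_spec()]
#' @param labels label table
#' @param dir optional output directory (`modules.tsv`)
#' @return data.frame gene_id, module_id
#' @export
generate_modules <- function(spec, labels, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  pools <- list(
    yome = sample(labels$gene_id[labels$category == "yome"]),
    well_annotated = sample(labels$gene_id[labels$category == "well_annotated"])
  )
  take <- function(cat) {
    if (length(pools[[cat]]) == 0) {
      cat <- setdiff(names(pools), cat)
      if (length(pools[[cat]]) == 0) return(NA_character_)
    }
    g <- pools[[cat]][1]
    pools[[cat]] <<- pools[[cat]][-1]
    g
  }
  rows <- list()
  for (m in seq_len(spec$n_modules)) {
    size <- sample(10:30, 1)
    base_cat <- sample(c("well_annotated", "yome"), 1, prob = c(.8, .2))
    other <- setdiff(c("well_annotated", "yome"), base_cat)
    draw_other <- stats::runif(size) < spec$mixing
    members <- vapply(draw_other,
                      function(o) take(if (o) other else base_cat), "")
    members <- members[!is.na(members)]
    if (length(members) < 10) break
    rows[[m]] <- data.frame(gene_id = members,
                            module_id = sprintf("M%02d", m),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), module_id = character())
  rownames(out) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(dir, "modules.tsv"))
  }
  out
}

#' Write a complete synthetic input set
#'
#' Convenience wrapper generating the knowledge-base suite, expression
#' compendium, positions and modules into one directory; the paths are
#' exactly what [run_pipeline()] consumes.
#'
#' @param spec a [synthetic_spec()]
#' @param dir output directory
#' @return named list of file paths (plus the in-memory objects,
#'   invisibly via attribute "objects")
#' @export
generate_synthetic_inputs <- function(spec, dir) {
  kb <- generate_kb_suite(spec, dir = dir)
  expr <- generate_expression(spec, kb$labels, dir = dir)
  pos <- generate_positions(spec, kb$labels, dir = dir)
  mods <- generate_modules(spec, kb$labels, dir = dir)
  paths <- list(
    ecocyc = file.path(dir, "ecocyc.tsv"),
    ecogene = file.path(dir, "ecogene.tsv"),
    uniprot = file.path(dir, "uniprot.tsv"),
    regulondb = file.path(dir, "regulondb.tsv"),
    overrides = file.path(dir, "overrides.tsv"),
    labels = file.path(dir, "labels.tsv"),
    counts = file.path(dir, "counts.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    samples = file.path(dir, "samples.tsv"),
    positions = file.path(dir, "positions.tsv"),
    modules = file.path(dir, "modules.tsv")
  )
  structure(paths, objects = list(kb = kb, expression = expr,
                                  positions = pos, modules = mods))
}
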