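test_that("canonical rows transcribe directly into features", {
  path <- write_feature_tsv(list(
    feature_row("ecocyc", "b0001", "thrL", "description", "thr operon leader peptide"),
    feature_row("ecocyc", "b0002", "thrA", "annotation_score", "3")
  ))
  parsed <- parse_feature_table(path, kb = "ecocyc")
  expect_equal(nrow(parsed$features), 2)
  expect_equal(nrow(parsed$errors), 0)
  expect_equal(parsed$features$feature_type[1], "description")
  expect_equal(parsed$features$feature_value[1], "thr operon leader peptide")
  expect_true(grepl("^[1-5]$", parsed$features$feature_value[2]))
})

test_that("malformed rows are collected with line numbers, not fatal", {
  path <- write_feature_tsv(list(
    feature_row("ecocyc", "b0001", "thrL", "description", "fine"),
    feature_row("ecocyc", "", "", "description", "no identifier"),
    feature_row("ecocyc", "b0003", "thrB", "made_up_type", "x"),
    feature_row("ecocyc", "b0004", "thrC", "annotation_score", "7")
  ))
  parsed <- parse_feature_table(path)
  expect_equal(nrow(parsed$features), 1)
  expect_equal(parsed$errors$line, c(3L, 4L, 5L))
  expect_match(parsed$errors$message[1], "neither locus_tag nor primary_name")
  expect_match(parsed$errors$message[2], "unknown feature_type")
  expect_match(parsed$errors$message[3], "integer 1-5")
})

test_that("a missing required column is a schema error", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("kb\tlocus_tag\tfeature_type", "ecocyc\tb0001\tdescription"), path)
  expect_error(parse_feature_table(path), "schema error.*primary_name")
})

test_that("fragments sharing a locus tag merge into one gene", {
  reg <- build_registry(rbind(
    feature_row("ecocyc", "b0001", "thrL", "description", "x"),
    feature_row("ecogene", "b0001", "thrL", "description", "y")
  ))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$gene_id, "b0001")
  expect_setequal(strsplit(reg$sources, ",")[[1]], c("ecocyc", "ecogene"))
})

test_that("fragments without a locus tag merge by exact name, others stay apart", {
  # 10-gene fixture; expected merges computed by brute-force name lookup
  frags <- do.call(rbind, c(
    lapply(1:9, function(i) {
      feature_row("ecocyc", sprintf("b%04d", i), paste0("gen", letters[i]),
                  "description", "x")
    }),
    list(feature_row("uniprot", "", "genc", "description", "x"),     # name hit
         feature_row("uniprot", "", "novel", "description", "x"))     # no hit
  ))
  lookup <- stats::setNames(sprintf("b%04d", 1:9), paste0("gen", letters[1:9]))
  expect_brute <- function(name) unname(lookup[name])
  reg <- build_registry(frags)
  expect_equal(nrow(reg), 10)  # 9 locus-tag genes + 1 surrogate
  hit <- reg[reg$primary_name == "genc", ]
  expect_equal(hit$gene_id, expect_brute("genc"))
  expect_true("uniprot" %in% strsplit(hit$sources, ",")[[1]])
  expect_true(any(grepl("^gene_", reg$gene_id)))  # surrogate for "novel"
})

test_that("conflicting primary names on one locus tag demote to synonyms", {
  reg <- build_registry(rbind(
    feature_row("ecocyc", "b1112", "dhaM", "description", "x"),
    feature_row("ecogene", "b1112", "ycgC", "description", "x")
  ))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$primary_name, "dhaM")  # source-precedence name wins
  expect_true("ycgC" %in% strsplit(reg$synonyms, "|", fixed = TRUE)[[1]])
  expect_true(any(grepl("conflicting primary names", attr(reg, "merge_log"))))
})

test_that("registry construction is idempotent and conserves features", {
  rows <- list(
    feature_row("ecocyc", "b0001", "thrL", "description", "a"),
    feature_row("ecocyc", "b0002", "thrA", "evidence", "assay"),
    feature_row("ecocyc", "b0001", "thrL", "summary", "b")
  )
  path <- write_feature_tsv(rows)
  once <- ingest_kb_tables(list(ecocyc = path))
  twice_path <- write_feature_tsv(c(rows, rows))
  twice <- ingest_kb_tables(list(ecocyc = twice_path))
  expect_equal(as.data.frame(once$genes), as.data.frame(twice$genes))
  expect_equal(nrow(once$features), 3)     # one per well-formed row
  expect_equal(nrow(twice$features), 6)
})

test_that("the feature store round-trips through its table serialization", {
  store <- store_from_rows(list(
    feature_row("ecocyc", "b0001", "thrL", "description", "thr leader"),
    feature_row("uniprot", "b0001", "thrL", "annotation_score", "2"),
    feature_row("ecogene", "b0002", "ycgX'", "description", "")
  ))
  dir <- tempfile()
  write_feature_store(store, dir)
  back <- read_feature_store(dir)
  expect_equal(as.data.frame(store$genes), as.data.frame(back$genes))
  expect_equal(attr(store$genes, "kb_names"), attr(back$genes, "kb_names"))
  expect_equal(store$features, back$features)
  expect_equal(store$provenance$kb, back$provenance$kb)
})

make_registry <- function(ids, names = ids) {
  build_registry(do.call(rbind, lapply(seq_along(ids), function(i) {
    feature_row("ecocyc", ids[i], names[i], "description", "x")
  })))
}

test_that("gene start sites are read from GFF3 with a gap report", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 10000",
    "chr\ttest\tgene\t100\t400\t.\t+\t.\tID=g1;locus_tag=b0001;Name=aaaA",
    "chr\ttest\tgene\t4500\t5000\t.\t-\t.\tID=g2;locus_tag=b0002;Name=bbbB",
    "chr\ttest\tgene\t9000\t9500\t.\t+\t.\tID=g3;locus_tag=b0003;Name=cccC"
  ), gff)
  reg <- make_registry(c("b0001", "b0002", "b0003", "b0004"))
  res <- load_positions(gff, reg)
  expect_equal(res$genome_length, 10000)
  expect_equal(nrow(res$positions), 3)
  got <- stats::setNames(res$positions$start, res$positions$gene_id)
  expect_equal(got[["b0001"]], 100)
  expect_equal(got[["b0002"]], 5000)  # minus strand: start site is the right end
  expect_equal(got[["b0003"]], 9000)
  expect_equal(res$gaps, "b0004")
})

test_that("GenBank flat files yield the same positions", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TESTCHR              10000 bp    DNA     circular BCT",
    "FEATURES             Location/Qualifiers",
    "     gene            100..400",
    "                     /gene=\"aaaA\"",
    "                     /locus_tag=\"b0001\"",
    "     gene            complement(4500..5000)",
    "                     /locus_tag=\"b0002\"",
    "ORIGIN",
    "//"
  ), gb)
  reg <- make_registry(c("b0001", "b0002"))
  res <- load_positions(gb, reg)
  expect_equal(res$genome_length, 10000)
  got <- stats::setNames(res$positions$start, res$positions$gene_id)
  expect_equal(got[["b0001"]], 100)
  expect_equal(got[["b0002"]], 5000)
})

test_that("out-of-range starts and namespace mismatches are errors", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 10000",
    "chr\ttest\tgene\t10500\t10900\t.\t+\t.\tID=g1;locus_tag=b0001"
  ), gff)
  reg <- make_registry("b0001")
  expect_error(load_positions(gff, reg), "outside")

  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 10000",
    "chr\ttest\tgene\t100\t400\t.\t+\t.\tID=g1;locus_tag=zzz9999"
  ), gff2)
  expect_error(load_positions(gff2, reg), "namespace mismatch")
})
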