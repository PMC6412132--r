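rules <- load_rules()

test_that("agreement and the four exception heuristics decide as specified", {
  # agreement with not-enough-information sources
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "ecogene", "uniprot"),
    c("well_annotated", "insufficient", "insufficient")))
  expect_equal(r[c("category", "basis")],
               list(category = "well_annotated", basis = "agreement"))

  # encyclopedia + protein knowledge base both well-annotated
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "uniprot", "ecogene"),
    c("well_annotated", "well_annotated", "yome")))
  expect_equal(r$category, "well_annotated")
  expect_equal(r$basis, "exception_ecocyc_uniprot")

  # definite disagreement without an override stays unresolved
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "ecogene"), c("yome", "well_annotated")))
  expect_equal(r$basis, "unresolved")
  expect_true(is.na(r$category))

  # strong transcription-factor evidence wins over a low-annotation vote
  r <- apply_consensus(assignment_rows(
    c("regulondb", "ecocyc"), c("well_annotated", "yome"),
    c("regulondb.tf_evidence.strong", "ecocyc.description.predicted")))
  expect_equal(r$category, "well_annotated")
  expect_equal(r$basis, "exception_regulondb")

  # assay-grade evidence overrides a keyword vote inside the same source
  r <- apply_consensus(assignment_rows(
    "ecocyc", "well_annotated",
    "ecocyc.description.predicted;ecocyc.evidence.assay"))
  expect_equal(r$basis, "exception_evidence")

  # insertion elements
  r <- apply_consensus(assignment_rows(
    "ecocyc", "well_annotated", "ecocyc.structured.ins_name"))
  expect_equal(r$basis, "exception_insertion")
})

test_that("exclusion is decided before any well-annotated exception", {
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "ecogene"), c("well_annotated", "excluded"),
    c("ecocyc.evidence.assay", "ecogene.structured.apostrophe")))
  expect_equal(r$category, "excluded")
})

test_that("only-insufficient genes default to the y-ome with low confidence", {
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "ecogene"), c("insufficient", "insufficient")))
  expect_equal(r$category, "yome")
  expect_equal(r$basis, "agreement")
  expect_true(r$low_confidence)
  expect_error(apply_consensus(assignment_rows(character(), character())),
               "at least one")
})

test_that("the override decides a disagreement; exceptions are order-independent", {
  r <- apply_consensus(assignment_rows(
    c("ecocyc", "ecogene"), c("yome", "well_annotated")), override = "yome")
  expect_equal(r[c("category", "basis")], list(category = "yome", basis = "manual"))

  # all exceptions output well_annotated, so whenever several can fire the
  # category is invariant to their serialization; permute the rows too
  a <- assignment_rows(
    c("ecocyc", "uniprot", "regulondb"),
    c("well_annotated", "well_annotated", "well_annotated"),
    c("ecocyc.evidence.assay;ecocyc.structured.insertion_flag",
      "uniprot.structured.annotation_score_high",
      "regulondb.tf_evidence.strong"))
  for (perm in list(1:3, 3:1, c(2, 1, 3), c(2, 3, 1))) {
    expect_equal(apply_consensus(a[perm, ])$category, "well_annotated")
  }
})

test_that("no-information detection covers phrases, emptiness and domain-only", {
  f <- function(ft, v) data.frame(feature_type = ft, value = v)
  expect_true(detect_no_info(f("summary",
    "No information about this protein was found by a literature search conducted on 23 February 2017"),
    rules))
  expect_true(detect_no_info(f("description", "Putative uncharacterized protein"), rules))
  expect_true(detect_no_info(rbind(f("domain_only", "DUF1479"),
                                   f("description", "")), rules))
  expect_false(detect_no_info(f("description", "predicted transporter"), rules))
  expect_false(detect_no_info(rbind(f("summary", "No information about this one"),
                                    f("description", "zinc-binding enzyme")), rules))
})

test_that("finalize yields a full partition and the override always wins", {
  records <- data.frame(
    gene_id = c("g1", "g2", "g3"), primary_name = c("yaaA", "abcB", "ycgC"),
    category = c("yome", "well_annotated", NA),
    basis = c("agreement", "agreement", "unresolved"),
    no_info = c(FALSE, FALSE, FALSE), low_confidence = FALSE,
    fired_rules = "", stringsAsFactors = FALSE)
  ov <- data.frame(gene_id = c("g3", "g2"), category = c("yome", "yome"),
                   justification = c("curated", "curated"),
                   stringsAsFactors = FALSE)
  expect_warning(final <- finalize(records, ov), "not unresolved")
  expect_setequal(final$category, c("yome"))
  expect_equal(final$basis[final$gene_id == "g2"], "manual")
  expect_equal(final$basis[final$gene_id == "g3"], "manual")
  expect_true(all(final$category %in% c("yome", "well_annotated", "excluded")))

  # strict mode names the uncovered gene; permissive mode flags it through
  expect_error(finalize(records, NULL, strict = TRUE), "g3")
  expect_warning(perm <- finalize(records, NULL, strict = FALSE), "permissive")
  expect_equal(perm$category[perm$gene_id == "g3"], "yome")
  expect_error(finalize(records,
    data.frame(gene_id = "g3", category = "yome", justification = "  ",
               stringsAsFactors = FALSE)), "justification")
})

test_that("consensus over a store flags no-info only inside the y-ome", {
  store <- store_from_rows(list(
    feature_row("ecocyc", "b0001", "ybiU", "summary",
                "No information about this protein was found"),
    feature_row("uniprot", "b0001", "ybiU", "description",
                "Putative uncharacterized protein"),
    feature_row("ecocyc", "b0002", "abcB", "evidence", "assay"),
    feature_row("ecocyc", "b0002", "abcB", "description", "")
  ))
  tbl <- consensus_table(categorize_store(store), store, rules)
  expect_equal(tbl$category[tbl$gene_id == "b0001"], "yome")
  expect_true(tbl$no_info[tbl$gene_id == "b0001"])
  expect_equal(tbl$category[tbl$gene_id == "b0002"], "well_annotated")
  expect_false(tbl$no_info[tbl$gene_id == "b0002"])  # empty text, but not yome
})
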