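rules <- load_rules()

test_that("keyword rules match case-insensitively and report every hit", {
  hits <- classify_feature(
    list(kb = "ecocyc", feature_type = "description", value = "Predicted transporter"),
    rules)
  expect_equal(hits$category, "yome")
  expect_equal(hits$rule_id, "ecocyc.description.predicted")

  hits <- classify_feature(
    list(kb = "ecocyc", feature_type = "evidence", value = "assay"), rules)
  expect_equal(hits$category, "well_annotated")
  expect_equal(hits$rule_id, "ecocyc.evidence.assay")

  none <- classify_feature(
    list(kb = "ecocyc", feature_type = "description", value = "ATP synthase subunit"),
    rules)
  expect_equal(nrow(none), 0)
})

test_that("word-mode rules respect word boundaries", {
  strong <- classify_feature(
    list(kb = "regulondb", feature_type = "tf_evidence", value = "Strong"), rules)
  expect_equal(strong$category, "well_annotated")
  not_word <- classify_feature(
    list(kb = "regulondb", feature_type = "tf_evidence", value = "headstrong"), rules)
  expect_equal(nrow(not_word), 0)
})

test_that("annotation scores map to categories with hard validation", {
  expect_equal(uniprot_score_rule(1), "yome")
  expect_equal(uniprot_score_rule(2), "yome")
  expect_equal(uniprot_score_rule(3), "insufficient")
  expect_equal(uniprot_score_rule(4), "well_annotated")
  expect_equal(uniprot_score_rule(5), "well_annotated")
  expect_error(uniprot_score_rule(0), "1..5")
  expect_error(uniprot_score_rule(6), "1..5")
  expect_error(uniprot_score_rule("x"), "1..5")
})

test_that("structured rules fire on flags, names and scores", {
  f <- function(ft, v = "x") data.frame(feature_type = ft, value = v)
  expect_equal(structured_rules(f("reaction_equation"), "ecocyc", "abcD", rules)$category,
               "well_annotated")
  expect_equal(structured_rules(f("description", ""), "ecogene", "ycgH'", rules)$category,
               "excluded")
  expect_equal(structured_rules(f("description", ""), "ecocyc", "insA", rules)$rule_id,
               "ecocyc.structured.ins_name")
  expect_equal(structured_rules(f("pseudogene_flag"), "ecocyc", "abcD", rules)$category,
               "excluded")
  score <- structured_rules(f("annotation_score", "2"), "uniprot", "abcD", rules)
  expect_equal(score$rule_id, "uniprot.structured.annotation_score_low")
  # score 3 carries no definite signal
  expect_equal(nrow(structured_rules(f("annotation_score", "3"), "uniprot", "abcD", rules)), 0)
})

test_that("within-source resolution follows precedence and records all rules", {
  f <- function(ft, v) data.frame(feature_type = ft, value = v)
  yome_only <- classify_gene_kb("g", "ecocyc", f("description", "hypothetical protein"),
                                "yaaA", rules)
  expect_equal(yome_only$category, "yome")

  both <- classify_gene_kb("g", "ecocyc",
                           rbind(f("description", "predicted enzyme"),
                                 f("evidence", "assay")), "yaaA", rules)
  expect_equal(both$category, "well_annotated")
  expect_setequal(both$fired_rules,
                  c("ecocyc.description.predicted", "ecocyc.evidence.assay"))

  empty <- classify_gene_kb("g", "ecocyc", f("description", "")[0, ], "yaaA", rules)
  expect_equal(empty$category, "insufficient")
  expect_length(empty$fired_rules, 0)
})

test_that("classification is deterministic and monotone under added evidence", {
  f <- data.frame(feature_type = "description", value = "predicted transporter")
  a <- classify_gene_kb("g", "ecocyc", f, "yaaA", rules)
  b <- classify_gene_kb("g", "ecocyc", f, "yaaA", rules)
  expect_identical(a, b)
  # adding a well-annotated trigger can only move the category up
  up <- classify_gene_kb("g", "ecocyc",
                         rbind(f, data.frame(feature_type = "evidence", value = "assay")),
                         "yaaA", rules)
  expect_equal(up$category, "well_annotated")
  more <- classify_gene_kb("g", "ecocyc",
                           rbind(f, data.frame(feature_type = "reaction_equation",
                                               value = "a -> b"),
                                 data.frame(feature_type = "evidence", value = "assay")),
                           "yaaA", rules)
  expect_equal(more$category, "well_annotated")
})

test_that("the vectorized store categorization agrees with per-gene calls", {
  store <- store_from_rows(list(
    feature_row("ecocyc", "b0001", "yaaA", "description", "hypothetical protein"),
    feature_row("ecocyc", "b0002", "abcB", "evidence", "assay"),
    feature_row("ecocyc", "b0002", "abcB", "description", "predicted thing"),
    feature_row("uniprot", "b0003", "abcC", "annotation_score", "5"),
    feature_row("ecogene", "b0004", "ycgH'", "description", ""),
    feature_row("ecocyc", "b0005", "insZ", "description", "mobile element"),
    feature_row("regulondb", "b0006", "regF", "tf_evidence", "Strong"),
    feature_row("ecogene", "b0007", "blaH", "description", "nothing special")
  ))
  got <- categorize_store(store)
  kb_names <- attr(store$genes, "kb_names")
  for (i in seq_len(nrow(got))) {
    gid <- got$gene_id[i]; kb <- got$kb[i]
    feats <- store$features[store$features$gene_id == gid & store$features$kb == kb,
                            c("feature_type", "value")]
    pn <- kb_names$primary_name[kb_names$gene_id == gid & kb_names$kb == kb][1]
    single <- classify_gene_kb(gid, kb, feats, pn, rules)
    expect_equal(got$category[i], single$category, label = paste(gid, kb))
    expect_setequal(strsplit(got$fired_rules[i], ";")[[1]], single$fired_rules)
  }
  expect_equal(got$category[got$gene_id == "b0004"], "excluded")
  expect_equal(got$category[got$gene_id == "b0005"], "well_annotated")
  expect_equal(got$category[got$gene_id == "b0007"], "insufficient")
})

test_that("rule subsets resolve exactly as the enumeration oracle says", {
  # 6 rules (2 per target) against a feature firing a chosen subset
  targets <- rep(c("yome", "well_annotated", "excluded"), each = 2)
  tr <- toy_rules(targets)
  words <- paste0("kw", seq_along(targets))
  for (bits in 0:63) {
    on <- which(bitwAnd(bits, 2^(0:5)) > 0)
    value <- paste(words[on], collapse = " ")
    f <- data.frame(feature_type = "description", value = value)
    got <- classify_gene_kb("g", "ecocyc", f, "abcD", tr)
    expect_equal(got$category, oracle_precedence(targets[on]),
                 label = sprintf("subset %d", bits))
  }
})
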