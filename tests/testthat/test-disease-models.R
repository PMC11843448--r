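# HPOA parsing and background phenotype frequencies.

hpoa_file <- function(rows) {
  header <- paste("database_id", "disease_name", "qualifier", "hpo_id",
                  "reference", "evidence", "onset", "frequency", sep = "\t")
  path <- tempfile(fileext = ".hpoa")
  writeLines(c("#comment line", header, rows), path)
  path
}

hpoa_row <- function(id, name, qualifier, hpo, freq) {
  paste(id, name, qualifier, hpo, "", "TAS", "", freq, sep = "\t")
}

test_that("parse_hpoa builds one model per disease with parsed frequencies", {
  path <- hpoa_file(c(
    hpoa_row("OMIM:100001", "disease one", "", "HP:0000002", "4/5"),
    hpoa_row("OMIM:100001", "disease one", "", "HP:0000003", ""),
    hpoa_row("OMIM:100001", "disease one", "NOT", "HP:0000004", ""),
    hpoa_row("OMIM:100002", "disease two", "", "HP:0000002", "45%"),
    hpoa_row("OMIM:100002", "disease two", "", "HP:0000005", "HP:0040282"),
    hpoa_row("ORPHA:1", "orpha disease", "", "HP:0000002", "")))
  corpus <- parse_hpoa(path)
  expect_named(corpus, c("OMIM:100001", "OMIM:100002"))  # ORPHA filtered
  m1 <- corpus[["OMIM:100001"]]
  expect_equal(m1$annotations,
               c("HP:0000002" = 0.8, "HP:0000003" = 1.0))  # empty -> default
  expect_equal(m1$excluded, "HP:0000004")
  m2 <- corpus[["OMIM:100002"]]
  expect_equal(unname(m2$annotations[["HP:0000002"]]), 0.45)
  expect_equal(unname(m2$annotations[["HP:0000005"]]), 0.545) # freq term
})

test_that("frequency edge cases: unparseable falls back, zero means absent", {
  path <- hpoa_file(c(
    hpoa_row("OMIM:100001", "d", "", "HP:0000002", "often"),
    hpoa_row("OMIM:100001", "d", "", "HP:0000003", "0/7")))
  expect_warning(corpus <- parse_hpoa(path), "unparseable frequency")
  m <- corpus[["OMIM:100001"]]
  expect_equal(unname(m$annotations[["HP:0000002"]]), 1.0)
  expect_false("HP:0000003" %in% names(m$annotations))
  expect_true("HP:0000003" %in% m$excluded)
})

test_that("a term asserted both present and NOT ends up excluded, with warning", {
  path <- hpoa_file(c(
    hpoa_row("OMIM:100001", "d", "", "HP:0000002", "1/2"),
    hpoa_row("OMIM:100001", "d", "NOT", "HP:0000002", "")))
  expect_warning(corpus <- parse_hpoa(path), "NOT wins")
  m <- corpus[["OMIM:100001"]]
  expect_false("HP:0000002" %in% names(m$annotations))
  expect_true("HP:0000002" %in% m$excluded)
  expect_length(intersect(names(m$annotations), m$excluded), 0L)
})

test_that("missing mandatory columns are a format error", {
  path <- tempfile()
  writeLines(c("database_id\tdisease_name", "OMIM:1\tx"), path)
  expect_error(parse_hpoa(path), "mandatory column")
})

test_that("background frequencies propagate annotations to ancestors", {
  hpo <- toy_hpo() # B,C under root A; D,E under B
  corpus <- list(
    disease_model("OMIM:000001", c("HP:0000004" = 1.0)),  # D -> B, A
    disease_model("OMIM:000002", c("HP:0000002" = 0.5)),  # B -> A
    disease_model("OMIM:000003", c("HP:0000003" = 1.0)),  # C -> A
    disease_model("OMIM:000004", c("HP:0000003" = 0.2)))  # C -> A
  bg <- background_frequencies(corpus, hpo)
  # brute-force count: B carried by diseases 1 (via D) and 2 -> 2/4
  expect_equal(unname(bg$freq[["HP:0000002"]]), 0.5)
  expect_equal(unname(bg$freq[["HP:0000001"]]), 1.0)       # root
  expect_equal(unname(bg$freq[["HP:0000005"]]), 1 / 8)     # floor 1/(2N)
  expect_equal(bg$n_diseases, 4L)
})

test_that("background frequencies are monotone along the ontology", {
  b <- synth_bundle()
  for (i in seq_len(nrow(b$hpo$edges))) {
    expect_gte(b$bg$freq[[b$hpo$edges$parent[i]]],
               b$bg$freq[[b$hpo$edges$child[i]]])
  }
  expect_true(all(b$bg$freq > 0 & b$bg$freq <= 1))
  expect_equal(unname(b$bg$freq[["HP:0000001"]]), 1.0)
})

test_that("annotated terms absent from the ontology are skipped with warning", {
  hpo <- toy_hpo()
  corpus <- list(disease_model("OMIM:000001",
                               c("HP:0000002" = 1, "HP:7777777" = 1)))
  expect_warning(bg <- background_frequencies(corpus, hpo),
                 "absent from ontology")
  expect_equal(unname(bg$freq[["HP:0000002"]]), 1.0)
})

test_that("corpus write -> parse round-trips models", {
  b <- synth_bundle()
  path <- tempfile(fileext = ".hpoa")
  write_hpoa(b$corpus, path)
  back <- parse_hpoa(path)
  expect_named(back, sort(names(b$corpus)))
  for (id in names(b$corpus)) {
    a0 <- b$corpus[[id]]$annotations
    a1 <- back[[id]]$annotations
    expect_equal(a1[sort(names(a1))], a0[sort(names(a0))])
    expect_equal(sort(back[[id]]$excluded), sort(b$corpus[[id]]$excluded))
  }
})

test_that("disease_model enforces frequency range and disjointness", {
  expect_error(disease_model("OMIM:1", c("HP:0000001" = 0)), "\\(0, 1\\]")
  expect_error(disease_model("OMIM:1", c("HP:0000001" = 1.2)), "\\(0, 1\\]")
  expect_error(disease_model("OMIM:1", c("HP:0000001" = 1),
                             excluded = "HP:0000001"), "both annotated")
})
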