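small_dict <- function() {
  leap_dictionary(
    attributes = list(
      primary_diagnosis = c("Malignant myoepithelioma", "Seromucinous carcinoma"),
      morphology = c("8982/3", "8474/3")),
    dependencies = list(list(
      key = "morphology", dependent = "primary_diagnosis",
      pairs = list(c("8982/3", "Malignant myoepithelioma"),
                   c("8474/3", "Seromucinous carcinoma")))))
}

test_that("dictionaries validate their own structure", {
  expect_error(leap_dictionary(list()), "named list")
  expect_error(leap_dictionary(list(a = character(0))), "empty allowable")
  expect_error(leap_dictionary(list(a = "x"),
                               list(list(key = "a", dependent = "b",
                                         pairs = list(c("x", "y"))))),
               "undeclared")
  expect_error(leap_dictionary(list(a = "x", b = "y"),
                               list(list(key = "a", dependent = "b",
                                         pairs = list(c("zz", "y"))))),
               "not allowable")
  # JSON round trip
  d <- small_dict()
  path <- withr::local_tempfile(fileext = ".json")
  leap_write_dictionary(d, path)
  expect_identical(leap_read_dictionary(path), d)
})

test_that("capitalization differences are distinguished from unknown terms", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "GENIE mapping")
  e1 <- leap_add_entity(st, ty, "m1")
  e2 <- leap_add_entity(st, ty, "m2")
  e3 <- leap_add_entity(st, ty, "m3")
  leap_add_attribute(st, "primary_diagnosis")
  leap_set_fact(st, e1, "primary_diagnosis", "Malignant Myoepithelioma")
  leap_set_fact(st, e2, "primary_diagnosis", "Malignant myoepithelioma")
  leap_set_fact(st, e3, "primary_diagnosis", "Completely different term")
  f <- leap_check_allowable_values(st, small_dict(), "GENIE mapping")
  expect_identical(nrow(f), 2L)
  expect_identical(f$category[f$entity == "m1"], "CAPITALIZATION_MISMATCH")
  expect_match(f$detail[f$entity == "m1"], "Malignant myoepithelioma")
  expect_identical(f$category[f$entity == "m3"], "UNKNOWN_TERM")
  expect_false("m2" %in% f$entity)
  # outer whitespace alone is not a finding
  e4 <- leap_add_entity(st, ty, "m4")
  leap_set_fact(st, e4, "primary_diagnosis", " Malignant myoepithelioma ")
  f2 <- leap_check_allowable_values(st, small_dict(), "GENIE mapping")
  expect_false("m4" %in% f2$entity)
})

test_that("dependent-field mismatches cite the rule and expected values", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "GENIE mapping")
  bad <- leap_add_entity(st, ty, "bad")
  ok <- leap_add_entity(st, ty, "ok")
  lone <- leap_add_entity(st, ty, "lone")
  leap_add_attribute(st, "primary_diagnosis")
  leap_add_attribute(st, "morphology")
  leap_set_fact(st, bad, "morphology", "8982/3")
  leap_set_fact(st, bad, "primary_diagnosis", "Seromucinous carcinoma")
  leap_set_fact(st, ok, "morphology", "8982/3")
  leap_set_fact(st, ok, "primary_diagnosis", "Malignant myoepithelioma")
  leap_set_fact(st, lone, "morphology", "8982/3")
  f <- leap_check_dependent_fields(st, small_dict(), "GENIE mapping")
  expect_identical(f$entity, "bad")
  expect_identical(f$category, "DEPENDENT_FIELD_MISMATCH")
  expect_identical(f$attribute, "primary_diagnosis")
  expect_match(f$detail, "morphology = '8982/3'")
  expect_match(f$detail, "Malignant myoepithelioma")
  expect_identical(attr(f, "incomplete_pairs"),
                   "lone: morphology/primary_diagnosis")
})

test_that("a value-level defect suppresses the dependent check for that pair", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "GENIE mapping")
  e <- leap_add_entity(st, ty, "m1")
  leap_add_attribute(st, "primary_diagnosis")
  leap_add_attribute(st, "morphology")
  leap_set_fact(st, e, "morphology", "8982/3")
  leap_set_fact(st, e, "primary_diagnosis", "malignant myoepithelioma")
  rep <- leap_validate(st, small_dict(), "GENIE mapping")
  expect_identical(unname(rep$counts[["CAPITALIZATION_MISMATCH"]]), 1L)
  expect_identical(unname(rep$counts[["DEPENDENT_FIELD_MISMATCH"]]), 0L)
  # no (entity, attribute) ever carries two value categories
  keys <- paste(rep$findings$entity, rep$findings$attribute)
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("validate unions the checks, counts categories, and stays read-only", {
  f <- fig2_store()
  ty <- leap_add_entity_type(f$store, "GENIE mapping")
  m1 <- leap_add_entity(f$store, ty, "MYEC|primary")
  leap_add_attribute(f$store, "morphology")
  leap_set_fact(f$store, m1, "morphology", "8982/3")
  leap_set_fact(f$store, m1, "primary_diagnosis", "seromucinous Carcinoma")
  m2 <- leap_add_entity(f$store, ty, "STMYEC|primary")
  leap_set_fact(f$store, m2, "morphology", "8982/3")
  leap_set_fact(f$store, m2, "primary_diagnosis", "Seromucinous carcinoma")
  leap_annotate_inaccurate(f$store, m2, "expert: wrong morphology")
  n0 <- f$store$n_changes
  rep <- leap_validate(f$store, small_dict(), "GENIE mapping")
  expect_identical(f$store$n_changes, n0)  # validation never mutates
  expect_identical(unname(rep$counts[c("CAPITALIZATION_MISMATCH",
                                       "DEPENDENT_FIELD_MISMATCH",
                                       "UNKNOWN_TERM",
                                       "ANNOTATED_INACCURATE")]),
                   c(1L, 1L, 0L, 1L))
  expect_setequal(rep$entities_needing_remediation,
                  c("MYEC|primary", "STMYEC|primary"))
  # deterministic report order: entity label, then attribute
  expect_false(is.unsorted(rep$findings$entity))
  # findings survive a JSON and a CSV write
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  leap_write_report(rep, jpath)
  leap_write_report(rep, cpath)
  expect_identical(leap_read_table(cpath), rep$findings)
  expect_identical(
    jsonlite::fromJSON(jpath)$counts$DEPENDENT_FIELD_MISMATCH, 1L)
})

test_that("a defect-free world validates to an empty report", {
  zero <- c(capitalization = 0, unknown_term = 0, dependent_mismatch = 0,
            annotated_inaccurate = 0)
  w <- leap_generate_world(leap_fixture_spec(seed = 21, n_codes = 15,
                                             defect_rates = zero))
  st <- leap_store(actor = "t")
  leap_load_world(st, w)
  rep <- leap_validate(st, w$dictionary, "GENIE mapping")
  expect_identical(nrow(rep$findings), 0L)
  expect_identical(sum(rep$counts), 0L)
  expect_length(rep$entities_needing_remediation, 0L)
})

test_that("seeded defects are recovered exactly, by entity, attribute and category", {
  for (seed in c(31, 32, 33)) {
    w <- leap_generate_world(leap_fixture_spec(seed = seed, n_codes = 40))
    st <- leap_store(actor = "t")
    leap_load_world(st, w)
    rep <- leap_validate(st, w$dictionary, "GENIE mapping")
    expect_identical(finding_keys(rep$findings), gt_keys(w))
    # counts agree with the ground truth per category
    gt_counts <- table(w$ground_truth$seeded_defects$category)
    for (cat in names(gt_counts)) {
      expect_identical(unname(rep$counts[[cat]]),
                       as.integer(gt_counts[[cat]]))
    }
  }
})

test_that("adding an allowable value never increases the finding count", {
  w <- leap_generate_world(leap_fixture_spec(seed = 44, n_codes = 30))
  st <- leap_store(actor = "t")
  leap_load_world(st, w)
  rep0 <- leap_validate(st, w$dictionary, "GENIE mapping")
  # admit one observed-but-unknown value into the dictionary
  unk <- rep0$findings[rep0$findings$category == "UNKNOWN_TERM", ]
  expect_gt(nrow(unk), 0L)
  d2 <- w$dictionary
  d2$attributes[[unk$attribute[[1]]]] <-
    c(d2$attributes[[unk$attribute[[1]]]], unk$observed[[1]])
  rep1 <- leap_validate(st, d2, "GENIE mapping")
  expect_lt(nrow(rep1$findings), nrow(rep0$findings))
})

test_that("store attributes outside the dictionary are metadata, not findings", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "GENIE mapping")
  e <- leap_add_entity(st, ty, "m1")
  leap_add_attribute(st, "oncotree_code")
  leap_set_fact(st, e, "oncotree_code", "MYEC")
  rep <- leap_validate(st, small_dict(), "GENIE mapping")
  expect_identical(nrow(rep$findings), 0L)
  expect_identical(rep$metadata$unchecked_attributes, "oncotree_code")
})
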