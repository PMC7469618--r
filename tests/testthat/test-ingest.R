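toy_classification <- function() {
  leap_classification("oncotree", "toy_v1", data.frame(
    code = c("TISSUE-X", "C1"),
    name = c("Tissue X", "Child one"),
    main_type = c("X cancer", "X cancer"),
    tissue = c("x", "x"),
    parent_code = c("", "TISSUE-X"),
    stringsAsFactors = FALSE))
}

test_that("classification tables validate codes and parents", {
  expect_error(leap_classification("s", "v", data.frame(code = "A")), "lack column")
  bad_dup <- data.frame(code = c("A", "A"), name = c("n", "n"),
                        main_type = c("m", "m"), tissue = c("t", "t"))
  expect_error(leap_classification("s", "v", bad_dup), "duplicate code")
  bad_parent <- data.frame(code = "A", name = "n", main_type = "m",
                           tissue = "t", parent_code = "GHOST")
  expect_error(leap_classification("s", "v", bad_parent), "not present")
})

test_that("loading a classification creates entities, facts, and parent links", {
  st <- leap_store(actor = "t")
  summ <- leap_load_classification(st, toy_classification())
  expect_identical(summ, list(entities_created = 2L, facts_created = 6L,
                              links_created = 1L))
  child <- leap_entity(st, "oncotree code", "C1")
  res <- leap_resolve(st, child)
  expect_identical(res$entries$name$value, "Child one")
  expect_identical(res$entries$name$provenance, "DIRECT")
  links <- leap_links(st)
  expect_identical(links$role, "parent")
  # the same version cannot be loaded twice
  expect_error(leap_load_classification(st, toy_classification()),
               "already loaded")
})

test_that("generated trees load with exact entity/fact/link counts", {
  w <- leap_generate_world(leap_fixture_spec(seed = 3, n_codes = 100))
  st <- leap_store(actor = "t")
  summ <- leap_load_classification(st, w$classification)
  expect_identical(summ$entities_created, 100L)
  expect_identical(summ$facts_created, 300L)
  n_roots <- sum(!nzchar(w$classification$records$parent_code))
  expect_identical(summ$links_created, 100L - n_roots)
})

test_that("mapping rows inherit GDC fields through links instead of copying", {
  w <- leap_generate_world(leap_fixture_spec(
    seed = 5, n_codes = 10, defect_rates = c(annotated_inaccurate = 0)))
  st <- leap_store(actor = "t")
  leap_load_world(st, w)
  mt_id <- leap_entity_types(st)$id[leap_entity_types(st)$name == "GENIE mapping"]
  map_ids <- leap_entities(st)$id[leap_entities(st)$entity_type_id == mt_id]
  facts <- leap_facts(st)
  # exactly the two identifying facts sit on each mapping entity
  expect_identical(sum(facts$entity_id %in% map_ids), 2L * nrow(w$sheet))
  # GDC descriptive values resolve as INHERITED with the provider on the path
  one <- leap_resolve(st, w$sheet$label[[1]])
  for (a in setdiff(leap_gdc_diagnosis_attributes(),
                    c("morphology", "tissue_or_organ_of_origin"))) {
    expect_identical(one$entries[[a]]$provenance, "INHERITED")
  }
  expect_identical(one$entries$primary_diagnosis$path[[2]],
                   w$sheet$morphology[[1]])
})

test_that("mapping sheets reject unknown sample types and duplicates atomically", {
  st <- leap_store(actor = "t")
  sheet <- leap_generate_world(leap_fixture_spec(seed = 2, n_codes = 3))$sheet
  bad <- sheet
  bad$sample_type[[2]] <- "weird"
  n0 <- st$n_changes
  expect_error(leap_load_mapping_sheet(st, bad), "unknown sample_type")
  expect_identical(st$n_changes, n0)
  dup <- rbind(sheet, sheet[1, ])
  expect_error(leap_load_mapping_sheet(st, dup), "duplicate")
  # contradictory carried values roll the whole import back
  contradiction <- sheet
  stopifnot(contradiction$morphology[[1]] == contradiction$morphology[[4]] ||
            nrow(contradiction) > 3)
  contradiction$primary_diagnosis[
    contradiction$morphology == contradiction$morphology[[1]]][2] <- "changed"
  if (sum(sheet$morphology == sheet$morphology[[1]]) > 1) {
    expect_error(leap_load_mapping_sheet(st, contradiction), "already carries")
    expect_identical(st$n_changes, n0)
  }
  # an empty sheet imports zeros
  empty <- sheet[0, ]
  summ <- leap_load_mapping_sheet(st, empty)
  expect_identical(summ$mappings_created, 0L)
  expect_identical(summ$links_created, 0L)
})

test_that("the dynamic pivot discovers columns and aborts on conflicts", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "thing")
  a <- leap_add_entity(st, ty, "A")
  leap_add_attribute(st, "x")
  leap_set_fact(st, a, "x", "v")
  tab <- leap_export_denormalized(st, "thing")
  expect_identical(dim(tab), c(1L, 2L))
  expect_identical(names(tab), c("label", "x"))
  expect_identical(tab$x, "v")
  # a second entity with more attributes widens the table dynamically
  b <- leap_add_entity(st, ty, "B")
  leap_add_attribute(st, "y")
  leap_set_fact(st, b, "y", "w")
  tab2 <- leap_export_denormalized(st, "thing")
  expect_identical(names(tab2), c("label", "x", "y"))
  expect_identical(tab2$y, c("", "w"))
  # explicit ordering is honored
  tab3 <- leap_export_denormalized(st, "thing", attribute_order = c("y", "x"))
  expect_identical(names(tab3), c("label", "y", "x"))
  expect_error(leap_export_denormalized(st, "thing", attribute_order = "zz"),
               "absent")
  # an inheritance conflict aborts the export naming the entity
  c1 <- leap_add_entity(st, ty, "C1")
  c2 <- leap_add_entity(st, ty, "C2")
  d <- leap_add_entity(st, ty, "D")
  leap_set_fact(st, c1, "x", "one")
  leap_set_fact(st, c2, "x", "two")
  leap_add_link(st, d, c1)
  leap_add_link(st, d, c2)
  expect_error(leap_export_denormalized(st, "thing"), "conflicts.*D")
})

test_that("pivot and unpivot are inverse on generated worlds", {
  w <- leap_generate_world(leap_fixture_spec(seed = 11, n_codes = 20))
  st <- leap_store(actor = "t")
  leap_load_world(st, w)
  ex <- leap_export_denormalized(st, "GENIE mapping")
  st2 <- leap_store(actor = "t2")
  leap_load_mapping_sheet(st2, ex)
  ex2 <- leap_export_denormalized(st2, "GENIE mapping")
  expect_identical(ex2, ex)
  # resolved sets agree entity by entity
  for (lab in ex$label[c(1, nrow(ex))]) {
    r1 <- as.data.frame(leap_resolve(st, leap_entity(st, "GENIE mapping", lab)))
    r2 <- as.data.frame(leap_resolve(st2, leap_entity(st2, "GENIE mapping", lab)))
    expect_identical(r2[order(r2$attribute), c("attribute", "value")],
                     r1[order(r1$attribute), c("attribute", "value")])
  }
})

test_that("delimited text round-trips quotes, delimiters, newlines and unicode", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(
    a = c("plain", "with,comma", "with \"quotes\"", "café 中文"),
    b = c("1", "", "tab\there", "emoji ✓"),
    stringsAsFactors = FALSE)
  leap_write_table(tab, path)
  expect_identical(leap_read_table(path), tab)
  # CRLF and LF parse identically
  lf <- withr::local_tempfile(fileext = ".csv")
  crlf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4"), lf, sep = "\n")
  writeChar("a,b\r\n1,2\r\n3,4\r\n", crlf, eos = NULL)
  expect_identical(leap_read_table(lf), leap_read_table(crlf))
  # TSV via extension
  tsv <- withr::local_tempfile(fileext = ".tsv")
  leap_write_table(tab[, "a", drop = FALSE], tsv)
  expect_identical(leap_read_table(tsv), tab[, "a", drop = FALSE])
  # fuzz: random unicode cells survive a round trip
  set.seed(42)
  pool <- c(letters, LETTERS, 0:9, ",", "\"", "'", ";", " ", "é",
            "世", "界", "☃")
  fuzz <- as.data.frame(replicate(4, vapply(1:50, function(i) {
    paste(sample(pool, sample(0:12, 1), replace = TRUE), collapse = "")
  }, ""), simplify = FALSE), stringsAsFactors = FALSE)
  names(fuzz) <- paste0("c", 1:4)
  fpath <- withr::local_tempfile(fileext = ".csv")
  leap_write_table(fuzz, fpath)
  expect_identical(leap_read_table(fpath), fuzz)
})

test_that("ragged rows are rejected with a clean error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "1,2,3"), path)
  expect_error(leap_read_table(path), "malformed|cannot read")
})

test_that("classification files round-trip through read/write", {
  path <- withr::local_tempfile(fileext = ".csv")
  cls <- toy_classification()
  leap_write_classification(cls, path)
  back <- leap_read_classification(path, "oncotree", "toy_v1")
  expect_identical(back, cls)
})
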