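test_that("entity types require nonempty unique names", {
  st <- leap_store(actor = "t")
  et <- leap_add_entity_type(st, "GDC morphology")
  expect_identical(et$name, "GDC morphology")
  expect_error(leap_add_entity_type(st, ""), "nonempty")
  leap_add_entity_type(st, "OncoTree code")
  expect_error(leap_add_entity_type(st, "OncoTree code"), "already exists")
})

test_that("entities enforce referential integrity and per-type uniqueness", {
  st <- leap_store(actor = "t")
  ot <- leap_add_entity_type(st, "OncoTree code")
  e <- leap_add_entity(st, ot, "MYEC")
  expect_identical(e$label, "MYEC")
  expect_error(leap_add_entity(st, "never created", "X"), "unknown entity type")
  expect_error(leap_add_entity(st, 999L, "X"), "unknown entity type")
  expect_error(leap_add_entity(st, ot, "MYEC"), "already exists")
  # same label under a different type is fine
  gm <- leap_add_entity_type(st, "GDC morphology")
  expect_silent(leap_add_entity(st, gm, "MYEC"))
})

test_that("facts reuse shared pairs and replace one value per attribute", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  b <- leap_add_entity(st, ty, "B")
  leap_add_attribute(st, "grade")
  leap_set_fact(st, a, "grade", "G2")
  leap_set_fact(st, b, "grade", "G2")
  # two entities, one shared (attribute, value) pair row
  expect_identical(nrow(leap_pairs(st)), 1L)
  expect_identical(length(unique(leap_facts(st)$pair_id)), 1L)
  # idempotent re-set: no new fact, no new history record
  n0 <- st$n_changes
  leap_set_fact(st, a, "grade", "G2")
  expect_identical(st$n_changes, n0)
  expect_identical(nrow(leap_facts(st)), 2L)
  # replacement keeps one fact per (entity, attribute) and records an UPDATE
  leap_set_fact(st, a, "grade", "G3")
  expect_identical(nrow(leap_facts(st)), 2L)
  ch <- leap_changes(st)
  expect_identical(ch$op[nrow(ch)], "UPDATE")
  expect_error(leap_set_fact(st, "nope", "grade", "G1"), "unknown entity")
  expect_error(leap_set_fact(st, a, "nope", "G1"), "unknown attribute")
})

test_that("links reject self-links, duplicates, and cycles naming the path", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  b <- leap_add_entity(st, ty, "B")
  c_ <- leap_add_entity(st, ty, "C")
  expect_error(leap_add_link(st, a, a), "self-link")
  leap_add_link(st, a, b)
  expect_error(leap_add_link(st, a, b), "already exists")
  leap_add_link(st, b, c_)
  err <- tryCatch(leap_add_link(st, c_, a), error = function(e) e)
  expect_match(conditionMessage(err), "cycle")
  expect_match(conditionMessage(err), "A -> B -> C")
  # nothing was written by the rejected calls
  expect_identical(nrow(leap_links(st)), 2L)
})

test_that("resolution inherits transitively with direct-overrides and nearest-wins", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  b <- leap_add_entity(st, ty, "B")
  c_ <- leap_add_entity(st, ty, "C")
  for (at in c("x", "y", "z")) leap_add_attribute(st, at)
  leap_set_fact(st, c_, "x", "from-C")
  leap_set_fact(st, c_, "y", "from-C")
  leap_set_fact(st, b, "x", "from-B")
  leap_set_fact(st, a, "z", "own")
  leap_add_link(st, a, b)
  leap_add_link(st, b, c_)
  res <- leap_resolve(st, a)
  # nearest provider wins for x; y comes through two hops; z is direct
  expect_identical(res$entries$x$value, "from-B")
  expect_identical(res$entries$x$path, c("A", "B"))
  expect_identical(res$entries$y$value, "from-C")
  expect_identical(res$entries$y$path, c("A", "B", "C"))
  expect_identical(res$entries$z$provenance, "DIRECT")
  # direct fact beats any inherited value
  leap_set_fact(st, a, "x", "mine")
  expect_identical(leap_resolve(st, a)$entries$x$value, "mine")
  # an isolated entity resolves to the empty set
  lone <- leap_add_entity(st, ty, "LONE")
  expect_length(leap_resolve(st, lone)$entries, 0L)
})

test_that("equal-distance disagreement is a hard conflict, not a tie-break", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  b <- leap_add_entity(st, ty, "B")
  c_ <- leap_add_entity(st, ty, "C")
  leap_add_attribute(st, "x")
  leap_set_fact(st, b, "x", "v1")
  leap_set_fact(st, c_, "x", "v2")
  leap_add_link(st, a, b)
  leap_add_link(st, a, c_)
  err <- tryCatch(leap_resolve(st, a), error = function(e) e)
  expect_s3_class(err, "leap_conflict_error")
  expect_identical(err$attribute, "x")
  expect_setequal(err$values, c("v1", "v2"))
  expect_identical(sort(vapply(err$paths, function(p) p[[2]], "")), c("B", "C"))
  # a direct fact dissolves the conflict
  leap_set_fact(st, a, "x", "mine")
  expect_identical(leap_resolve(st, a)$entries$x$value, "mine")
})

test_that("resolution matches the exhaustive oracle on random DAG stores", {
  for (seed in 1:40) {
    world <- random_dag_store(seed)
    expect_resolution_matches_oracle(world)
  }
})

test_that("one pair update cascades to every entity that inherits it", {
  f <- fig2_store()
  pair <- leap_get_pair(f$store, "primary_diagnosis", "Malignant myoepithelioma")
  s <- leap_update_pair_value(f$store, pair, "myoepithelioma, malignant")
  expect_identical(s$rows_updated, 1L)
  expect_setequal(s$affected_entities, c("8982/3", "MYEC", "STMYEC"))
  for (e in list(f$myec, f$stmyec)) {
    expect_identical(leap_resolve(f$store, e)$entries$primary_diagnosis$value,
                     "myoepithelioma, malignant")
  }
  # updating to the value already stored is a no-op
  pair2 <- leap_get_pair(f$store, "primary_diagnosis", "myoepithelioma, malignant")
  s2 <- leap_update_pair_value(f$store, pair2, "myoepithelioma, malignant")
  expect_identical(s2$rows_updated, 0L)
  expect_length(s2$affected_entities, 0L)
})

test_that("a star of k inheritors reports k+1 affected entities", {
  k <- 5L
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  hub <- leap_add_entity(st, ty, "HUB")
  leap_add_attribute(st, "x")
  leap_set_fact(st, hub, "x", "old")
  for (i in seq_len(k)) {
    leap_add_link(st, leap_add_entity(st, ty, paste0("S", i)), hub)
  }
  s <- leap_update_pair_value(st, leap_get_pair(st, "x", "old"), "new")
  expect_identical(length(s$affected_entities), k + 1L)
  # oracle: reversed-reachability from the holder, plus the holder
  edges <- leap_links(st)[, c("source_id", "target_id")]
  names(edges) <- c("src", "dst")
  expect_identical(length(oracle_dependents(nrow(leap_entities(st)), edges,
                                            hub$id)) + 1L,
                   length(s$affected_entities))
})

test_that("pair-value collisions merge facts onto the existing pair (or reject)", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  b <- leap_add_entity(st, ty, "B")
  leap_add_attribute(st, "x")
  leap_set_fact(st, a, "x", "old")
  leap_set_fact(st, b, "x", "target")
  p_old <- leap_get_pair(st, "x", "old")
  expect_error(
    leap_update_pair_value(st, p_old, "target", on_collision = "reject"),
    "already exists")
  s <- leap_update_pair_value(st, p_old, "target")
  expect_true(s$merged)
  expect_identical(s$rows_updated, 1L)
  expect_identical(nrow(leap_pairs(st)), 1L)
  expect_identical(length(unique(leap_facts(st)$pair_id)), 1L)
  expect_identical(leap_resolve(st, a)$entries$x$value, "target")
})

test_that("dependents are the reversed transitive closure", {
  f <- fig2_store()
  deps <- leap_dependents(f$store, f$morph)
  expect_setequal(deps$label, c("MYEC", "STMYEC"))
  expect_identical(nrow(leap_dependents(f$store, f$myec)), 0L)
  for (seed in 41:50) {
    world <- random_dag_store(seed)
    for (i in seq_len(world$n)) {
      got <- leap_dependents(world$store, world$entities[[i]])
      want <- oracle_dependents(world$n, world$edges, i)
      expect_setequal(got$label, paste0("E", want, recycle0 = TRUE))
    }
  }
})

test_that("referenced rows cannot be deleted and ids are never reused", {
  st <- leap_store(actor = "t")
  ty <- leap_add_entity_type(st, "node")
  a <- leap_add_entity(st, ty, "A")
  leap_add_attribute(st, "x")
  fact <- leap_set_fact(st, a, "x", "v")
  expect_error(leap_delete(st, "entity", a$id), "still reference")
  expect_error(leap_delete(st, "entity_type", ty$id), "still reference")
  expect_error(leap_delete(st, "pair", leap_get_pair(st, "x", "v")$id),
               "still reference")
  leap_delete(st, "fact", fact$id)
  leap_delete(st, "entity", a$id)
  a2 <- leap_add_entity(st, ty, "A2")
  expect_gt(a2$id, a$id)
})

test_that("replaying an identical fact script yields identical resolved sets", {
  build <- function() {
    st <- leap_store(actor = "t")
    ty <- leap_add_entity_type(st, "node")
    es <- lapply(c("A", "B", "C"), function(l) leap_add_entity(st, ty, l))
    for (a in c("x", "y")) leap_add_attribute(st, a)
    script <- list(list(1, "x", "1"), list(2, "x", "2"), list(1, "x", "3"),
                   list(3, "y", "1"), list(1, "x", "3"), list(2, "y", "2"))
    for (s in script) leap_set_fact(st, es[[s[[1]]]], s[[2]], s[[3]])
    leap_add_link(st, es[[1]], es[[2]])
    lapply(es, function(e) as.data.frame(leap_resolve(st, e)))
  }
  expect_identical(build(), build())
})
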