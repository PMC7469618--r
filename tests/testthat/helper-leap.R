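# Shared fixtures and independent oracles for the test suite.

# The worked cascade example: two tree codes sharing one morphology.
fig2_store <- function() {
  st <- leap_store(actor = "tester")
  ot <- leap_add_entity_type(st, "OncoTree code")
  gm <- leap_add_entity_type(st, "GDC morphology")
  myec <- leap_add_entity(st, ot, "MYEC")
  stmyec <- leap_add_entity(st, ot, "STMYEC")
  morph <- leap_add_entity(st, gm, "8982/3")
  leap_add_attribute(st, "primary_diagnosis")
  leap_set_fact(st, morph, "primary_diagnosis", "Malignant myoepithelioma")
  leap_add_link(st, myec, morph)
  leap_add_link(st, stmyec, morph)
  list(store = st, myec = myec, stmyec = stmyec, morph = morph)
}

relation_dfs <- function(store) {
  list(entity_types = leap_entity_types(store),
       entities = leap_entities(store)[, c("id", "entity_type_id", "label")],
       attributes = leap_attributes(store),
       pairs = leap_pairs(store)[, c("id", "attribute_id", "value")],
       facts = leap_facts(store),
       links = leap_links(store))
}

# ---- independent resolution oracle --------------------------------------
# Brute force over a plain edge/fact representation: BFS shortest distance
# to every provider, union facts over reachable entities, direct (distance
# 0) overrides inherited, nearest provider wins, equal-distance
# disagreement is a conflict. Shares no code with the package internals.
oracle_distances <- function(n, edges, start) {
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(edges$dst[edges$src %in% frontier])
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# facts: data.frame(entity, attr, value). Returns list(values = named chr,
# conflicts = chr vector of attributes with equal-distance disagreement).
oracle_resolve <- function(n, edges, facts, start) {
  dist <- oracle_distances(n, edges, start)
  values <- character(0)
  conflicts <- character(0)
  for (a in unique(facts$attr)) {
    fa <- facts[facts$attr == a & is.finite(dist[facts$entity]), , drop = FALSE]
    if (nrow(fa) == 0) next
    dmin <- min(dist[fa$entity])
    vals <- unique(fa$value[dist[fa$entity] == dmin])
    if (length(vals) > 1 && dmin > 0) {
      conflicts <- c(conflicts, a)
    } else {
      values[[a]] <- vals[[1]]
    }
  }
  list(values = values, conflicts = conflicts)
}

oracle_dependents <- function(n, edges, target) {
  rev_edges <- data.frame(src = edges$dst, dst = edges$src)
  dist <- oracle_distances(n, rev_edges, target)
  setdiff(which(is.finite(dist)), target)
}

# Random acyclic store: entities E1..En (edges only from lower to higher
# index, so the digraph is a DAG by construction), a handful of attributes
# with values drawn from a small shared pool (to exercise pair reuse and
# genuine conflicts). Returns the store plus the plain representation the
# oracles consume.
random_dag_store <- function(seed, n_max = 12, k_attrs = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  st <- leap_store(actor = "oracle")
  ty <- leap_add_entity_type(st, "node")
  attrs <- paste0("attr", seq_len(k_attrs))
  for (a in attrs) leap_add_attribute(st, a)
  ents <- lapply(seq_len(n), function(i) leap_add_entity(st, ty, paste0("E", i)))
  facts <- data.frame(entity = integer(0), attr = character(0),
                      value = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    for (a in attrs) {
      if (runif(1) < 0.35) {
        v <- paste0("v", sample(3, 1))
        leap_set_fact(st, ents[[i]], a, v)
        facts <- rbind(facts, data.frame(entity = i, attr = a, value = v,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  edges <- data.frame(src = integer(0), dst = integer(0))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (runif(1) < 0.25) {
        leap_add_link(st, ents[[i]], ents[[j]])
        edges <- rbind(edges, data.frame(src = i, dst = j))
      }
    }
  }
  list(store = st, entities = ents, n = n, edges = edges, facts = facts,
       attrs = attrs)
}

# compare package resolution with the oracle for every entity of a
# random_dag_store world; errors out with an informative message on any
# divergence
expect_resolution_matches_oracle <- function(world) {
  for (i in seq_len(world$n)) {
    expected <- oracle_resolve(world$n, world$edges, world$facts, i)
    got <- tryCatch(leap_resolve(world$store, world$entities[[i]]),
                    leap_conflict_error = function(e) e)
    if (length(expected$conflicts) > 0) {
      expect_s3_class(got, "leap_conflict_error")
      expect_true(got$attribute %in% expected$conflicts)
    } else {
      expect_false(inherits(got, "leap_conflict_error"),
                   label = sprintf("unexpected conflict for E%d", i))
      by_name <- function(x) if (length(x)) x[order(names(x))] else unname(x)
      vals <- vapply(got$entries, `[[`, "", "value")
      expect_identical(by_name(vals), by_name(expected$values),
                       label = sprintf("resolved values of E%d", i))
      # every inherited path starts at the entity and follows real links
      for (a in names(got$entries)) {
        e <- got$entries[[a]]
        path_ids <- match(e$path, vapply(world$entities, `[[`, "", "label"))
        expect_identical(path_ids[[1]], i)
        if (length(path_ids) > 1) {
          for (s in seq_len(length(path_ids) - 1)) {
            expect_true(any(world$edges$src == path_ids[[s]] &
                            world$edges$dst == path_ids[[s + 1]]))
          }
        }
      }
    }
  }
}

# a random but always-valid mutation script of `n_ops` successful writes;
# returns the store and a data.frame snapshot captured after every op
scripted_mutations <- function(seed, n_ops = 50) {
  set.seed(seed)
  st <- leap_store(actor = "script")
  ty <- leap_add_entity_type(st, "node")
  for (a in paste0("a", 1:4)) leap_add_attribute(st, a)
  ents <- list()
  snapshots <- list()
  ops_done <- 0
  while (ops_done < n_ops) {
    kind <- sample(c("entity", "fact", "link", "pair_update"), 1,
                   prob = c(0.3, 0.4, 0.2, 0.1))
    ok <- tryCatch({
      switch(kind,
        entity = {
          ents[[length(ents) + 1]] <- leap_add_entity(
            st, ty, paste0("N", length(ents) + 1))
          TRUE
        },
        fact = {
          if (length(ents) == 0) FALSE else {
            leap_set_fact(st, ents[[sample(length(ents), 1)]],
                          paste0("a", sample(4, 1)), paste0("v", sample(5, 1)))
            TRUE
          }
        },
        link = {
          if (length(ents) < 2) FALSE else {
            ij <- sort(sample(length(ents), 2))
            leap_add_link(st, ents[[ij[1]]], ents[[ij[2]]])
            TRUE
          }
        },
        pair_update = {
          p <- leap_pairs(st)
          if (nrow(p) == 0) FALSE else {
            row <- p[sample(nrow(p), 1), ]
            leap_update_pair_value(st, row$id, paste0("v", sample(9, 1)))
            TRUE
          }
        })
    }, error = function(e) FALSE)
    if (isTRUE(ok)) {
      ops_done <- ops_done + 1
      snapshots[[ops_done]] <- list(ts = leap_changes(st)$ts[st$n_changes],
                                    state = relation_dfs(st))
    }
  }
  list(store = st, snapshots = snapshots)
}

# findings vs. ground truth as comparable key sets
finding_keys <- function(df, cols = c("entity", "attribute", "category")) {
  sort(do.call(paste, c(unname(df[cols]), sep = "\r", recycle0 = TRUE)))
}

gt_keys <- function(world) {
  gt <- world$ground_truth$seeded_defects
  sort(do.call(paste, c(unname(gt[c("entity_label", "attribute", "category")]),
                        sep = "\r", recycle0 = TRUE)))
}
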