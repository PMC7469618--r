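# Core LEAP operations: entity types, entities, attributes, pairs, facts,
# links, inheritance-aware resolution and cascading pair updates.

#' Register an entity type
#'
#' @param store A writable `leap_store`.
#' @param name Nonempty type name, unique within the store
#'   (e.g. `"OncoTree code"`, `"GDC morphology"`).
#' @return The new entity-type record as a list (`id`, `name`).
#' @export
leap_add_entity_type <- function(store, name) {
  .check_writable(store)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("entity type name must be a nonempty string", call. = FALSE)
  }
  tab <- store$tables$entity_type
  if (length(.tbl_which(tab, "name", name)) > 0L) {
    stop(sprintf("entity type '%s' already exists", name), call. = FALSE)
  }
  row <- list(id = .next_id(store, "entity_type"), name = name)
  .leap_apply(store, "entity_type", "INSERT", row)
  invisible(row)
}

#' Register an attribute
#'
#' @param store A writable `leap_store`.
#' @param name Nonempty attribute name, unique within the store
#'   (e.g. `"primary_diagnosis"`).
#' @return The new attribute record as a list (`id`, `name`).
#' @export
leap_add_attribute <- function(store, name) {
  .check_writable(store)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("attribute name must be a nonempty string", call. = FALSE)
  }
  tab <- store$tables$attribute
  if (length(.tbl_which(tab, "name", name)) > 0L) {
    stop(sprintf("attribute '%s' already exists", name), call. = FALSE)
  }
  row <- list(id = .next_id(store, "attribute"), name = name)
  .leap_apply(store, "attribute", "INSERT", row)
  invisible(row)
}

.ensure_attribute <- function(store, name) {
  idx <- .tbl_which(store$tables$attribute, "name", name)
  if (length(idx) > 0L) {
    return(list(id = .tbl_col(store$tables$attribute, "id")[idx], name = name))
  }
  leap_add_attribute(store, name)
}

.ensure_entity_type <- function(store, name) {
  idx <- .tbl_which(store$tables$entity_type, "name", name)
  if (length(idx) > 0L) {
    return(list(id = .tbl_col(store$tables$entity_type, "id")[idx], name = name))
  }
  leap_add_entity_type(store, name)
}

#' Create an entity
#'
#' @param store A writable `leap_store`.
#' @param entity_type An entity type (record, id, or name); must already exist.
#' @param label Nonempty label, unique within the type (e.g. `"MYEC"`,
#'   `"8982/3"`).
#' @return The new entity record as a list (`id`, `entity_type_id`, `label`).
#' @export
leap_add_entity <- function(store, entity_type, label) {
  .check_writable(store)
  type_id <- .as_entity_type_id(store, entity_type)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("entity label must be a nonempty string", call. = FALSE)
  }
  tab <- store$tables$entity
  clash <- .tbl_which(tab, "label", label)
  if (any(.tbl_col(tab, "entity_type_id")[clash] == type_id)) {
    stop(sprintf("entity '%s' already exists for this entity type", label),
         call. = FALSE)
  }
  row <- list(id = .next_id(store, "entity"), entity_type_id = type_id,
              label = label)
  .leap_apply(store, "entity", "INSERT", row)
  invisible(row)
}

#' Look up an entity by type and label
#'
#' @param store A `leap_store`.
#' @param entity_type Entity type (record, id, or name).
#' @param label Entity label.
#' @return The entity record as a list, or an error if absent.
#' @export
leap_entity <- function(store, entity_type, label) {
  type_id <- .as_entity_type_id(store, entity_type)
  tab <- store$tables$entity
  idx <- intersect(.tbl_which(tab, "label", label),
                   .tbl_which(tab, "entity_type_id", type_id))
  if (length(idx) != 1L) {
    stop(sprintf("no entity '%s' of that type", label), call. = FALSE)
  }
  .tbl_row(tab, idx, .leap_tables$entity)
}

#' Look up a reusable attribute:value pair
#'
#' @param store A `leap_store`.
#' @param attribute Attribute (record, id, or name).
#' @param value Pair value.
#' @return The pair record as a list, or an error if absent.
#' @export
leap_get_pair <- function(store, attribute, value) {
  attr_id <- .as_attribute_id(store, attribute)
  tab <- store$tables$pair
  idx <- intersect(.tbl_which(tab, "value", value),
                   .tbl_which(tab, "attribute_id", attr_id))
  if (length(idx) != 1L) {
    stop(sprintf("no pair (%s, '%s')", attribute, value), call. = FALSE)
  }
  .tbl_row(tab, idx, .leap_tables$pair)
}

.ensure_pair <- function(store, attr_id, value) {
  tab <- store$tables$pair
  idx <- intersect(.tbl_which(tab, "value", value),
                   .tbl_which(tab, "attribute_id", attr_id))
  if (length(idx) == 1L) return(.tbl_row(tab, idx, .leap_tables$pair))
  row <- list(id = .next_id(store, "pair"), attribute_id = attr_id,
              value = value)
  .leap_apply(store, "pair", "INSERT", row)
  row
}

#' Assign an attribute value to an entity
#'
#' Pairs (attribute:value combinations) are reusable: if the combination
#' already exists the fact references the existing pair row, so two entities
#' sharing a value share one pair. An entity holds at most one direct fact
#' per attribute; a second assignment replaces the first (the replacement is
#' recorded in history). Re-assigning the identical value is a no-op.
#'
#' @param store A writable `leap_store`.
#' @param entity Entity (record, id, or unique label).
#' @param attribute Attribute (record, id, or name); must already exist.
#' @param value Character value.
#' @return The fact record as a list (`id`, `entity_id`, `pair_id`),
#'   invisibly for no-ops.
#' @export
leap_set_fact <- function(store, entity, attribute, value) {
  .check_writable(store)
  entity_id <- .as_entity_id(store, entity)
  attr_id <- .as_attribute_id(store, attribute)
  if (!is.character(value) || length(value) != 1L || is.na(value)) {
    stop("fact value must be a single string", call. = FALSE)
  }
  pair <- .ensure_pair(store, attr_id, value)
  ftab <- store$tables$fact
  fidx <- .tbl_which(ftab, "entity_id", entity_id)
  if (length(fidx) > 0L) {
    pair_ids <- .tbl_col(ftab, "pair_id")[fidx]
    ptab <- store$tables$pair
    fattr <- .tbl_col(ptab, "attribute_id")[match(pair_ids, .tbl_col(ptab, "id"))]
    hit <- fidx[fattr == attr_id]
    if (length(hit) == 1L) {
      existing <- .tbl_row(ftab, hit, .leap_tables$fact)
      if (existing$pair_id == pair$id) return(invisible(existing))
      row <- list(id = existing$id, entity_id = entity_id, pair_id = pair$id)
      .leap_apply(store, "fact", "UPDATE", row)
      return(invisible(row))
    }
  }
  row <- list(id = .next_id(store, "fact"), entity_id = entity_id,
              pair_id = pair$id)
  .leap_apply(store, "fact", "INSERT", row)
  invisible(row)
}

# Entities reachable from `from` over (optionally reversed) links.
.reachable <- function(store, from, reverse = FALSE) {
  ltab <- store$tables$link
  src <- .tbl_col(ltab, if (reverse) "target_id" else "source_id")
  dst <- .tbl_col(ltab, if (reverse) "source_id" else "target_id")
  seen <- from
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- setdiff(dst[src %in% frontier], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  setdiff(seen, from)
}

#' Link two entities for attribute inheritance
#'
#' Adds a directed edge from `source` (the inheritor) to `target` (the
#' provider). The link digraph must stay acyclic; self-links and duplicate
#' edges are rejected. Links compose transitively during resolution.
#'
#' @param store A writable `leap_store`.
#' @param source,target Entities (records, ids, or unique labels).
#' @param role Optional free-text role stored on the link; ignored during
#'   resolution.
#' @return The link record as a list.
#' @export
leap_add_link <- function(store, source, target, role = NA_character_) {
  .check_writable(store)
  src <- .as_entity_id(store, source)
  dst <- .as_entity_id(store, target)
  if (src == dst) {
    stop(sprintf("self-link rejected for entity '%s'",
                 .entity_label(store, src)), call. = FALSE)
  }
  ltab <- store$tables$link
  dup <- intersect(.tbl_which(ltab, "source_id", src),
                   .tbl_which(ltab, "target_id", dst))
  if (length(dup) > 0L) {
    stop(sprintf("link %s -> %s already exists",
                 .entity_label(store, src), .entity_label(store, dst)),
         call. = FALSE)
  }
  # adding src -> dst creates a cycle iff src is already reachable from dst
  if (src %in% .reachable(store, dst)) {
    path <- .link_path(store, dst, src)
    labels <- vapply(c(src, path), function(i) .entity_label(store, i), "")
    stop(sprintf("link rejected: it would close the cycle %s",
                 paste(labels, collapse = " -> ")), call. = FALSE)
  }
  row <- list(id = .next_id(store, "link"), source_id = src, target_id = dst,
              role = role)
  .leap_apply(store, "link", "INSERT", row)
  invisible(row)
}

# one shortest path from -> to over links (entity ids, inclusive)
.link_path <- function(store, from, to) {
  ltab <- store$tables$link
  src <- .tbl_col(ltab, "source_id")
  dst <- .tbl_col(ltab, "target_id")
  parent <- list()
  seen <- from
  frontier <- from
  while (length(frontier) > 0L && !(to %in% seen)) {
    nxt <- integer(0)
    for (f in sort(frontier)) {
      for (t in sort(dst[src == f])) {
        if (!(t %in% seen) && !(t %in% nxt)) {
          parent[[as.character(t)]] <- f
          nxt <- c(nxt, t)
        }
      }
    }
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (!(to %in% seen)) return(integer(0))
  path <- to
  while (path[1L] != from) {
    path <- c(parent[[as.character(path[1L])]], path)
  }
  path
}

.leap_conflict <- function(entity_label, attribute, values, paths) {
  msg <- sprintf(
    "conflicting inherited values for attribute '%s' on entity '%s': %s",
    attribute, entity_label,
    paste(sprintf("'%s' via %s", values,
                  vapply(paths, paste, "", collapse = " -> ")),
          collapse = " ; "))
  stop(structure(class = c("leap_conflict_error", "error", "condition"),
                 list(message = msg, call = NULL, entity = entity_label,
                      attribute = attribute, values = values, paths = paths)))
}

# direct facts of one entity, in fact-table (insertion) order
.direct_facts <- function(store, entity_id) {
  ftab <- store$tables$fact
  ptab <- store$tables$pair
  atab <- store$tables$attribute
  fidx <- .tbl_which(ftab, "entity_id", entity_id)
  pair_ids <- .tbl_col(ftab, "pair_id")[fidx]
  pidx <- match(pair_ids, .tbl_col(ptab, "id"))
  attr_ids <- .tbl_col(ptab, "attribute_id")[pidx]
  list(attribute_id = attr_ids,
       attribute = .tbl_col(atab, "name")[match(attr_ids, .tbl_col(atab, "id"))],
       value = .tbl_col(ptab, "value")[pidx],
       pair_id = pair_ids)
}

#' Resolve an entity's attributes, inheritance included
#'
#' Returns the entity's direct facts plus, for every attribute it does not
#' set directly, the value inherited through outgoing links (transitively).
#' Precedence: a direct fact always wins; among inherited providers the
#' nearest one (shortest link path) wins; if two providers at the same
#' shortest distance disagree on an attribute, resolution fails with a
#' `leap_conflict_error` listing the attribute, both values and both paths
#' rather than silently picking one.
#'
#' @param store A `leap_store`.
#' @param entity Entity (record, id, or unique label).
#' @return An object of class `leap_resolved`: a list with `entity_id`,
#'   `label`, and `entries`, a named list (one per attribute) of
#'   `list(value, provenance, path, pair_id, provider_id)` where provenance
#'   is `"DIRECT"` or `"INHERITED"` and `path` is the chain of entity labels
#'   from the entity to the provider.
#' @export
leap_resolve <- function(store, entity) {
  entity_id <- .as_entity_id(store, entity)
  .resolve_one(.resolve_ctx(store), entity_id)
}

# Precomputed lookup structures for bulk resolution: per-entity fact
# indices, pair/attribute columns aligned with the fact table, and the
# link adjacency, all keyed by entity id.
.resolve_ctx <- function(store) {
  etab <- store$tables$entity
  ftab <- store$tables$fact
  ptab <- store$tables$pair
  atab <- store$tables$attribute
  ltab <- store$tables$link
  eid <- .tbl_col(etab, "id")
  labels <- .tbl_col(etab, "label")
  names(labels) <- as.character(eid)
  fpair <- .tbl_col(ftab, "pair_id")
  pidx <- match(fpair, .tbl_col(ptab, "id"))
  fattr_id <- .tbl_col(ptab, "attribute_id")[pidx]
  list(labels = labels,
       facts_by_entity = split(seq_along(fpair), .tbl_col(ftab, "entity_id")),
       fattr_id = fattr_id,
       fattr = .tbl_col(atab, "name")[match(fattr_id, .tbl_col(atab, "id"))],
       fval = .tbl_col(ptab, "value")[pidx],
       fpair = fpair,
       adj = split(.tbl_col(ltab, "target_id"), .tbl_col(ltab, "source_id")))
}

.resolve_one <- function(ctx, entity_id) {
  key <- as.character(entity_id)
  label <- ctx$labels[[key]]
  entries <- list()
  for (j in ctx$facts_by_entity[[key]]) {
    entries[[ctx$fattr[[j]]]] <- list(
      value = ctx$fval[[j]], provenance = "DIRECT", path = label,
      attribute_id = ctx$fattr_id[[j]], pair_id = ctx$fpair[[j]],
      provider_id = entity_id)
  }
  paths <- list()
  paths[[key]] <- entity_id
  seen <- entity_id
  frontier <- entity_id
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (f in sort(frontier)) {
      for (t in sort(ctx$adj[[as.character(f)]])) {
        if (!(t %in% seen) && !(t %in% nxt)) {
          paths[[as.character(t)]] <- c(paths[[as.character(f)]], t)
          nxt <- c(nxt, t)
        }
      }
    }
    if (length(nxt) == 0L) break
    # this level's facts, grouped by attribute; nearest level wins, and
    # disagreement within one level is a hard conflict, not a tie-break
    nxt <- sort(nxt)
    fidx <- unlist(lapply(as.character(nxt), function(e) ctx$facts_by_entity[[e]]))
    providers_of <- rep(nxt, times = vapply(as.character(nxt), function(e)
      length(ctx$facts_by_entity[[e]]), 0L))
    for (aid in sort(unique(ctx$fattr_id[fidx]))) {
      sel <- fidx[ctx$fattr_id[fidx] == aid]
      prov <- providers_of[ctx$fattr_id[fidx] == aid]
      aname <- ctx$fattr[[sel[[1L]]]]
      if (!is.null(entries[[aname]])) next  # already resolved nearer
      values <- ctx$fval[sel]
      if (length(unique(values)) > 1L) {
        plabels <- lapply(prov, function(p) {
          unname(ctx$labels[as.character(paths[[as.character(p)]])])
        })
        .leap_conflict(label, aname, values, plabels)
      }
      entries[[aname]] <- list(
        value = values[[1L]], provenance = "INHERITED",
        path = unname(ctx$labels[as.character(paths[[as.character(prov[[1L]])]])]),
        attribute_id = aid, pair_id = ctx$fpair[[sel[[1L]]]],
        provider_id = prov[[1L]])
    }
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  structure(list(entity_id = entity_id, label = label, entries = entries),
            class = "leap_resolved")
}

#' @export
print.leap_resolved <- function(x, ...) {
  cat(sprintf("<leap_resolved> entity '%s' (%d attributes)\n",
              x$label, length(x$entries)))
  for (a in names(x$entries)) {
    e <- x$entries[[a]]
    prov <- if (e$provenance == "DIRECT") "direct" else
      paste0("via ", paste(e$path[-1L], collapse = " -> "))
    cat(sprintf("  %s = '%s'  [%s]\n", a, e$value, prov))
  }
  invisible(x)
}

#' @export
as.data.frame.leap_resolved <- function(x, ...) {
  if (length(x$entries) == 0L) {
    return(data.frame(attribute = character(0), value = character(0),
                      provenance = character(0), path = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    attribute = names(x$entries),
    value = vapply(x$entries, `[[`, "", "value"),
    provenance = vapply(x$entries, `[[`, "", "provenance"),
    path = vapply(x$entries, function(e) paste(e$path, collapse = " -> "), ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a resolved attribute set to JSON
#'
#' Flat object keyed by attribute name, each entry carrying `value`,
#' `provenance` and `path`.
#'
#' @param resolved A `leap_resolved` object.
#' @return A JSON string.
#' @export
leap_resolved_json <- function(resolved) {
  out <- lapply(resolved$entries, function(e) {
    list(value = e$value, provenance = e$provenance,
         path = paste(e$path, collapse = " -> "))
  })
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
}

#' Entities that inherit from an entity
#'
#' The transitive closure over reversed links: every entity that can reach
#' `entity` through one or more links, excluding the entity itself.
#'
#' @param store A `leap_store`.
#' @param entity Entity (record, id, or unique label).
#' @return A `data.frame` of entity rows (possibly empty).
#' @export
leap_dependents <- function(store, entity) {
  entity_id <- .as_entity_id(store, entity)
  ids <- sort(.reachable(store, entity_id, reverse = TRUE))
  ent <- leap_entities(store)
  ent[ent$id %in% ids, , drop = FALSE]
}

#' Change a pair's value and cascade it to every inheritor
#'
#' Updates one attribute:value pair row in place. Because facts reference
#' pairs and links inherit facts, a single pair update propagates to every
#' entity whose resolved set references that pair, directly or through
#' links -- the single-point-update property of the framework.
#'
#' If the new value collides with an existing pair of the same attribute,
#' `on_collision = "merge"` (default) repoints the referencing facts onto
#' the existing pair and deletes the now-duplicate row, preserving the
#' one-update cascade; `"reject"` errors instead.
#'
#' @param store A writable `leap_store`.
#' @param pair A pair record (see [leap_get_pair()]) or pair id.
#' @param new_value Replacement value.
#' @param on_collision `"merge"` or `"reject"`.
#' @param dry_run If `TRUE`, report what would change without mutating.
#' @return A `leap_change_summary`: `rows_updated` (pair rows modified),
#'   `affected_entities` (labels of every entity whose resolved set
#'   referenced the pair), `merged`.
#' @export
leap_update_pair_value <- function(store, pair, new_value,
                                   on_collision = c("merge", "reject"),
                                   dry_run = FALSE) {
  .check_writable(store)
  on_collision <- match.arg(on_collision)
  ptab <- store$tables$pair
  pid <- if (is.list(pair)) as.integer(pair$id) else as.integer(pair)
  idx <- .tbl_which(ptab, "id", pid)
  if (length(idx) != 1L) stop(sprintf("unknown pair id %d", pid), call. = FALSE)
  row <- .tbl_row(ptab, idx, .leap_tables$pair)
  summary <- function(rows, affected, merged) {
    structure(list(rows_updated = rows, affected_entities = affected,
                   merged = merged), class = "leap_change_summary")
  }
  if (identical(row$value, new_value)) {
    return(summary(0L, character(0), FALSE))
  }
  aname <- leap_attributes(store)$name[
    match(row$attribute_id, leap_attributes(store)$id)]
  # entities whose resolution references this pair, before the update
  ftab <- store$tables$fact
  holders <- .tbl_col(ftab, "entity_id")[.tbl_which(ftab, "pair_id", pid)]
  candidates <- sort(unique(c(holders, unlist(lapply(holders, function(h)
    .reachable(store, h, reverse = TRUE))))))
  ctx <- .resolve_ctx(store)
  affected <- candidates[vapply(candidates, function(e) {
    res <- .resolve_one(ctx, e)
    entry <- res$entries[[aname]]
    !is.null(entry) && entry$pair_id == pid
  }, logical(1))]
  affected_labels <- sort(vapply(affected, function(i) .entity_label(store, i), ""))
  clash <- intersect(.tbl_which(ptab, "value", new_value),
                     .tbl_which(ptab, "attribute_id", row$attribute_id))
  merged <- length(clash) > 0L
  if (merged && on_collision == "reject") {
    stop(sprintf("pair (%s, '%s') already exists; refusing to merge",
                 aname, new_value), call. = FALSE)
  }
  if (dry_run) return(summary(1L, affected_labels, merged))
  if (merged) {
    keep_id <- .tbl_col(ptab, "id")[clash]
    for (f in .tbl_which(ftab, "pair_id", pid)) {
      frow <- .tbl_row(ftab, f, .leap_tables$fact)
      frow$pair_id <- keep_id
      .leap_apply(store, "fact", "UPDATE", frow)
    }
    .leap_apply(store, "pair", "DELETE", list(id = pid))
  } else {
    .leap_apply(store, "pair", "UPDATE",
                list(id = pid, attribute_id = row$attribute_id,
                     value = new_value))
  }
  summary(1L, affected_labels, merged)
}

#' @export
print.leap_change_summary <- function(x, ...) {
  cat(sprintf("<leap_change_summary> rows_updated = %d%s\n", x$rows_updated,
              if (x$merged) " (merged onto existing pair)" else ""))
  if (length(x$affected_entities) > 0L) {
    cat("  affected entities:", paste(x$affected_entities, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Delete a row from a LEAP relation
#'
#' Deletion is rejected while any live row still references the target
#' (referential integrity). Identifiers are never reused after deletion.
#'
#' @param store A writable `leap_store`.
#' @param table One of `"entity_type"`, `"entity"`, `"attribute"`, `"pair"`,
#'   `"fact"`, `"link"`.
#' @param id Row id.
#' @return Invisibly, the deleted row image.
#' @export
leap_delete <- function(store, table, id) {
  .check_writable(store)
  table <- match.arg(table, names(.leap_tables))
  id <- as.integer(id)
  tab <- store$tables[[table]]
  idx <- .tbl_which(tab, "id", id)
  if (length(idx) != 1L) {
    stop(sprintf("no %s row with id %d", table, id), call. = FALSE)
  }
  refs <- switch(table,
    entity_type = length(.tbl_which(store$tables$entity, "entity_type_id", id)),
    attribute = length(.tbl_which(store$tables$pair, "attribute_id", id)),
    entity = length(.tbl_which(store$tables$fact, "entity_id", id)) +
      length(.tbl_which(store$tables$link, "source_id", id)) +
      length(.tbl_which(store$tables$link, "target_id", id)),
    pair = length(.tbl_which(store$tables$fact, "pair_id", id)),
    0L)
  if (refs > 0L) {
    stop(sprintf("cannot delete %s id %d: %d row(s) still reference it",
                 table, id, refs), call. = FALSE)
  }
  old <- .tbl_row(tab, idx, .leap_tables[[table]])
  .leap_apply(store, table, "DELETE", list(id = id))
  invisible(old)
}
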