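# Relation schemas. The six LEAP relations: entity types, entities,
# attributes, attribute:value pairs, the fact join table (no entity-type
# reference -- that lives on the entity), and directed links.
.leap_tables <- list(
  entity_type = c(id = "integer", name = "character"),
  attribute   = c(id = "integer", name = "character"),
  entity      = c(id = "integer", entity_type_id = "integer", label = "character"),
  pair        = c(id = "integer", attribute_id = "integer", value = "character"),
  fact        = c(id = "integer", entity_id = "integer", pair_id = "integer"),
  link        = c(id = "integer", source_id = "integer", target_id = "integer",
                  role = "character")
)

.leap_schema_version <- 1L

`%||%` <- function(a, b) if (is.null(a)) b else a

.default_actor <- function() {
  Sys.getenv("LEAP_ACTOR", unset = Sys.info()[["user"]] %||% "unknown")
}

# ---- column-store tables -------------------------------------------------

.new_table <- function(schema) {
  tab <- new.env(parent = emptyenv())
  tab$.n <- 0L
  for (col in names(schema)) assign(col, vector(schema[[col]], 0L), envir = tab)
  tab
}

.tbl_n <- function(tab) tab$.n

.tbl_col <- function(tab, col) {
  v <- get(col, envir = tab)
  if (length(v) > tab$.n) v[seq_len(tab$.n)] else v
}

.tbl_insert <- function(tab, row, schema) {
  i <- tab$.n + 1L
  for (col in names(schema)) {
    v <- get(col, envir = tab)
    val <- row[[col]]
    v[[i]] <- if (is.null(val) || (length(val) == 1L && is.na(val))) NA else val
    assign(col, v, envir = tab)
  }
  tab$.n <- i
  invisible(i)
}

.tbl_update <- function(tab, idx, row, schema) {
  for (col in names(schema)) {
    if (col == "id" || is.null(row[[col]])) next
    v <- get(col, envir = tab)
    v[[idx]] <- row[[col]]
    assign(col, v, envir = tab)
  }
  invisible(idx)
}

.tbl_delete <- function(tab, idx, schema) {
  keep <- setdiff(seq_len(tab$.n), idx)
  for (col in names(schema)) assign(col, get(col, envir = tab)[keep], envir = tab)
  tab$.n <- length(keep)
  invisible(NULL)
}

.tbl_row <- function(tab, idx, schema) {
  out <- vector("list", length(schema))
  names(out) <- names(schema)
  for (col in names(schema)) out[[col]] <- get(col, envir = tab)[[idx]]
  out
}

.tbl_df <- function(tab, schema) {
  cols <- lapply(names(schema), function(col) .tbl_col(tab, col))
  names(cols) <- names(schema)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.tbl_which <- function(tab, col, value) {
  which(.tbl_col(tab, col) == value)
}

# ---- store object --------------------------------------------------------

#' Create an in-memory LEAP store
#'
#' A LEAP store holds six relations -- entity types, entities, attributes,
#' attribute:value pairs, facts (entity to pair assignments) and directed
#' entity-to-entity links through which attributes are inherited. Every
#' mutation passes through a single interception layer that enforces
#' referential integrity and uniqueness and appends exactly one change
#' record to an append-only history, so the full state at any past instant
#' can be reconstructed (see [leap_as_of()]).
#'
#' @param actor Free-text attribution recorded on every change record.
#'   Defaults to the `LEAP_ACTOR` environment variable or the OS user.
#' @return An object of class `leap_store`.
#' @seealso [leap_open()] for a file-backed store.
#' @export
#' @examples
#' st <- leap_store()
#' ot <- leap_add_entity_type(st, "OncoTree code")
#' leap_add_entity(st, ot, "MYEC")
leap_store <- function(actor = NULL) {
  st <- new.env(parent = emptyenv())
  st$tables <- lapply(.leap_tables, .new_table)
  st$changes <- vector("list", 64L)
  st$n_changes <- 0L
  counters <- rep(1L, length(.leap_tables))
  names(counters) <- names(.leap_tables)
  st$counters <- counters
  st$actor <- actor %||% .default_actor()
  st$readonly <- FALSE
  st$path <- NULL
  st$created_at <- as.numeric(Sys.time())
  class(st) <- "leap_store"
  st
}

.check_writable <- function(store) {
  if (isTRUE(store$readonly)) {
    stop("this store is a read-only snapshot; mutations are not allowed",
         call. = FALSE)
  }
}

.next_id <- function(store, table) {
  id <- store$counters[[table]]
  store$counters[[table]] <- id + 1L
  id
}

.bump_counter <- function(store, table, id) {
  if (id >= store$counters[[table]]) store$counters[[table]] <- id + 1L
}

# Monotone UTC timestamp (numeric seconds, microsecond granularity).
.leap_now <- function(store) {
  t <- as.numeric(Sys.time())
  if (store$n_changes > 0L) {
    last <- store$changes[[store$n_changes]]$ts
    if (t <= last) t <- last + 1e-6
  }
  t
}

# The single mutation funnel. All writes -- user-facing operations and
# history replay alike -- go through here; each call applies one row-level
# change and appends one change record, so no code path can bypass history.
.leap_apply <- function(store, table, op, row, rec = NULL) {
  tab <- store$tables[[table]]
  schema <- .leap_tables[[table]]
  old <- NULL
  new <- NULL
  if (op == "INSERT") {
    .tbl_insert(tab, row, schema)
    new <- lapply(row[names(schema)], function(v) {
      if (is.null(v) || (length(v) == 1L && is.na(v))) NA else v
    })
    names(new) <- names(schema)
  } else {
    idx <- .tbl_which(tab, "id", row$id)
    if (length(idx) != 1L) {
      stop(sprintf("internal error: %s row id %s not found for %s",
                   table, row$id, op), call. = FALSE)
    }
    old <- .tbl_row(tab, idx, schema)
    if (op == "UPDATE") {
      .tbl_update(tab, idx, row, schema)
      new <- .tbl_row(tab, idx, schema)
    } else if (op == "DELETE") {
      .tbl_delete(tab, idx, schema)
    } else {
      stop("internal error: unknown operation ", op, call. = FALSE)
    }
  }
  if (is.null(rec)) {
    rec <- list(seq = store$n_changes + 1L, table = table, row_id = row$id,
                op = op, old = old, new = new, ts = .leap_now(store),
                actor = store$actor)
  }
  store$n_changes <- store$n_changes + 1L
  store$changes[[store$n_changes]] <- rec
  .bump_counter(store, table, row$id)
  invisible(rec)
}

.leap_records <- function(store) {
  if (store$n_changes == 0L) return(list())
  store$changes[seq_len(store$n_changes)]
}

# Rebuild a store by folding change records from scratch.
.leap_replay <- function(records, actor = NULL, created_at = NULL) {
  st <- leap_store(actor = actor)
  if (!is.null(created_at)) st$created_at <- created_at
  for (rec in records) {
    row <- rec$new %||% rec$old
    .leap_apply(st, rec$table, rec$op, row, rec = rec)
  }
  st
}

# All-or-nothing execution of `f(store)`: capture the full relation state
# (column vectors are copy-on-write, so the capture is cheap), run f, and
# restore the captured state on any error before rethrowing.
.store_capture <- function(store) {
  list(
    tables = lapply(names(.leap_tables), function(t) {
      tab <- store$tables[[t]]
      cols <- lapply(names(.leap_tables[[t]]), function(col) get(col, envir = tab))
      names(cols) <- names(.leap_tables[[t]])
      list(n = tab$.n, cols = cols)
    }),
    changes = store$changes,
    n_changes = store$n_changes,
    counters = store$counters)
}

.store_restore <- function(store, snap) {
  names(snap$tables) <- names(.leap_tables)
  for (t in names(.leap_tables)) {
    tab <- store$tables[[t]]
    tab$.n <- snap$tables[[t]]$n
    for (col in names(snap$tables[[t]]$cols)) {
      assign(col, snap$tables[[t]]$cols[[col]], envir = tab)
    }
  }
  store$changes <- snap$changes
  store$n_changes <- snap$n_changes
  store$counters <- snap$counters
  invisible(store)
}

.leap_transaction <- function(store, f) {
  .check_writable(store)
  snap <- .store_capture(store)
  tryCatch(f(store), error = function(e) {
    .store_restore(store, snap)
    stop(e)
  })
}

# ---- accessors -----------------------------------------------------------

#' Tabular views of the LEAP relations
#'
#' Each accessor returns the current live rows of one relation as a plain
#' `data.frame`. These are copies; mutating them does not touch the store.
#'
#' @param store A `leap_store`.
#' @return A `data.frame` with one row per live record.
#' @export
leap_entity_types <- function(store) .tbl_df(store$tables$entity_type, .leap_tables$entity_type)

#' @rdname leap_entity_types
#' @export
leap_entities <- function(store) {
  ent <- .tbl_df(store$tables$entity, .leap_tables$entity)
  et <- .tbl_df(store$tables$entity_type, .leap_tables$entity_type)
  ent$entity_type <- et$name[match(ent$entity_type_id, et$id)]
  ent
}

#' @rdname leap_entity_types
#' @export
leap_attributes <- function(store) .tbl_df(store$tables$attribute, .leap_tables$attribute)

#' @rdname leap_entity_types
#' @export
leap_pairs <- function(store) {
  p <- .tbl_df(store$tables$pair, .leap_tables$pair)
  at <- .tbl_df(store$tables$attribute, .leap_tables$attribute)
  p$attribute <- at$name[match(p$attribute_id, at$id)]
  p
}

#' @rdname leap_entity_types
#' @export
leap_facts <- function(store) .tbl_df(store$tables$fact, .leap_tables$fact)

#' @rdname leap_entity_types
#' @export
leap_links <- function(store) .tbl_df(store$tables$link, .leap_tables$link)

#' @export
print.leap_store <- function(x, ...) {
  counts <- vapply(x$tables, .tbl_n, integer(1))
  cat("<leap_store>",
      if (isTRUE(x$readonly)) "(read-only snapshot)" else "", "\n")
  if (!is.null(x$path)) cat("  file:", x$path, "\n")
  cat(sprintf("  %d entity types, %d entities, %d attributes, %d pairs, %d facts, %d links\n",
              counts[["entity_type"]], counts[["entity"]], counts[["attribute"]],
              counts[["pair"]], counts[["fact"]], counts[["link"]]))
  cat(sprintf("  %d change records\n", x$n_changes))
  invisible(x)
}

# ---- argument coercion ---------------------------------------------------

.as_entity_type_id <- function(store, entity_type) {
  tab <- store$tables$entity_type
  if (is.list(entity_type) && !is.null(entity_type$id)) {
    id <- as.integer(entity_type$id)
  } else if (is.numeric(entity_type)) {
    id <- as.integer(entity_type)
  } else if (is.character(entity_type) && length(entity_type) == 1L) {
    idx <- .tbl_which(tab, "name", entity_type)
    if (length(idx) == 0L) {
      stop(sprintf("unknown entity type '%s'", entity_type), call. = FALSE)
    }
    return(.tbl_col(tab, "id")[idx])
  } else {
    stop("cannot interpret entity type argument", call. = FALSE)
  }
  if (length(.tbl_which(tab, "id", id)) == 0L) {
    stop(sprintf("unknown entity type id %d", id), call. = FALSE)
  }
  id
}

.as_attribute_id <- function(store, attribute) {
  tab <- store$tables$attribute
  if (is.list(attribute) && !is.null(attribute$id)) {
    id <- as.integer(attribute$id)
  } else if (is.numeric(attribute)) {
    id <- as.integer(attribute)
  } else if (is.character(attribute) && length(attribute) == 1L) {
    idx <- .tbl_which(tab, "name", attribute)
    if (length(idx) == 0L) {
      stop(sprintf("unknown attribute '%s'", attribute), call. = FALSE)
    }
    return(.tbl_col(tab, "id")[idx])
  } else {
    stop("cannot interpret attribute argument", call. = FALSE)
  }
  if (length(.tbl_which(tab, "id", id)) == 0L) {
    stop(sprintf("unknown attribute id %d", id), call. = FALSE)
  }
  id
}

.as_entity_id <- function(store, entity) {
  tab <- store$tables$entity
  if (is.list(entity) && !is.null(entity$id)) {
    id <- as.integer(entity$id)
  } else if (is.numeric(entity)) {
    id <- as.integer(entity)
  } else if (is.character(entity) && length(entity) == 1L) {
    idx <- .tbl_which(tab, "label", entity)
    if (length(idx) == 0L) {
      stop(sprintf("unknown entity '%s'", entity), call. = FALSE)
    }
    if (length(idx) > 1L) {
      stop(sprintf(
        "entity label '%s' is ambiguous across entity types; pass an entity object or id",
        entity), call. = FALSE)
    }
    return(.tbl_col(tab, "id")[idx])
  } else {
    stop("cannot interpret entity argument", call. = FALSE)
  }
  if (length(.tbl_which(tab, "id", id)) == 0L) {
    stop(sprintf("unknown entity id %d", id), call. = FALSE)
  }
  id
}

.entity_label <- function(store, id) {
  idx <- .tbl_which(store$tables$entity, "id", id)
  .tbl_col(store$tables$entity, "label")[idx]
}
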