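# Durable persistence and temporal reconstruction. A store file is an
# append-only log of change records; the live relations are the fold of the
# log, and any past state is the fold of a prefix. Uniqueness, referential
# integrity and acyclicity are enforced by the operation layer every write
# passes through, so no mutation can bypass history capture.

.leap_file_format <- "leap-store"

#' Open (or create) a file-backed LEAP store
#'
#' The on-disk format is a single JSON file holding the complete ordered
#' change history; opening replays it into the live relations. Reopening a
#' store after writes reproduces identical contents. Saving writes to a
#' temporary file first and renames it into place, so a failed save never
#' leaves a partially written store.
#'
#' @param path File path for the store.
#' @param create_if_missing Create an empty store when `path` does not exist.
#' @param actor Attribution recorded on subsequent change records.
#' @return A `leap_store` bound to `path`.
#' @export
leap_open <- function(path, create_if_missing = TRUE, actor = NULL) {
  if (file.exists(path)) return(.leap_read(path, actor = actor))
  if (!create_if_missing) {
    stop(sprintf("no store at '%s' (create_if_missing = FALSE)", path),
         call. = FALSE)
  }
  st <- leap_store(actor = actor)
  st$path <- path
  leap_save(st)
  st
}

#' Save a LEAP store to its file
#'
#' @param store A `leap_store`.
#' @param path Target path; defaults to the path the store was opened from.
#' @return Invisibly, the path written.
#' @export
leap_save <- function(store, path = store$path) {
  if (is.null(path)) {
    stop("store has no path; pass `path` explicitly", call. = FALSE)
  }
  payload <- list(
    format = .leap_file_format,
    schema_version = .leap_schema_version,
    created_at = store$created_at,
    changes = lapply(.leap_records(store), function(r) {
      r$old <- r$old %||% NULL
      r$new <- r$new %||% NULL
      r
    })
  )
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not move saved store into place at '%s'", path),
         call. = FALSE)
  }
  store$path <- path
  invisible(path)
}

.coerce_record <- function(r) {
  fix_img <- function(img, schema) {
    if (is.null(img)) return(NULL)
    for (col in names(schema)) {
      if (schema[[col]] == "integer" && !is.null(img[[col]])) {
        img[[col]] <- as.integer(img[[col]])
      }
      if (!is.null(img[[col]]) && is.na(img[[col]])) img[[col]] <- NA
    }
    img[names(schema)]
  }
  schema <- .leap_tables[[r$table]]
  if (is.null(schema)) {
    stop(sprintf("store file references unknown relation '%s'", r$table),
         call. = FALSE)
  }
  list(seq = as.integer(r$seq), table = r$table, row_id = as.integer(r$row_id),
       op = r$op, old = fix_img(r$old, schema), new = fix_img(r$new, schema),
       ts = as.numeric(r$ts), actor = r$actor %||% "unknown")
}

.leap_read <- function(path, actor = NULL) {
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("'%s' is not a readable LEAP store (%s)",
                   path, conditionMessage(e)), call. = FALSE)
    })
  if (!identical(raw$format, .leap_file_format)) {
    stop(sprintf("'%s' is not a LEAP store file", path), call. = FALSE)
  }
  ver <- as.integer(raw$schema_version %||% 0L)
  if (ver != .leap_schema_version) {
    stop(sprintf(
      "store schema version %d does not match supported version %d; export from the original version and re-import",
      ver, .leap_schema_version), call. = FALSE)
  }
  records <- lapply(raw$changes, .coerce_record)
  st <- tryCatch(
    .leap_replay(records, actor = actor,
                 created_at = as.numeric(raw$created_at %||% 0)),
    error = function(e) {
      stop(sprintf("'%s' contains an inconsistent change history (%s)",
                   path, conditionMessage(e)), call. = FALSE)
    })
  st$path <- path
  st
}

#' The change history as a data frame
#'
#' One row per change record, in sequence order. `old` and `new` are list
#' columns holding full row images (an `UPDATE`'s `old` equals the previous
#' image of that row; `INSERT` has no `old`, `DELETE` no `new`). History is
#' append-only: no public operation modifies or removes records.
#'
#' @param store A `leap_store`.
#' @return A `data.frame` with columns `seq`, `table`, `row_id`, `op`, `ts`
#'   (numeric UTC seconds), `actor`, and list columns `old`, `new`.
#' @export
leap_changes <- function(store) {
  recs <- .leap_records(store)
  data.frame(
    seq = vapply(recs, `[[`, 0L, "seq"),
    table = vapply(recs, `[[`, "", "table"),
    row_id = vapply(recs, `[[`, 0L, "row_id"),
    op = vapply(recs, `[[`, "", "op"),
    ts = vapply(recs, `[[`, 0, "ts"),
    actor = vapply(recs, `[[`, "", "actor"),
    old = I(lapply(recs, `[[`, "old")),
    new = I(lapply(recs, `[[`, "new")),
    stringsAsFactors = FALSE)
}

#' Reconstruct the store as of a past instant
#'
#' Folds every change record with timestamp at or before `time` into a
#' fresh, read-only snapshot. [leap_resolve()] and the exporters work on
#' snapshots exactly as on live stores, using only data visible at `time`.
#' A time before the store's creation yields an empty snapshot.
#'
#' @param store A `leap_store`.
#' @param time A `POSIXct`, or numeric seconds since the epoch.
#' @return A read-only `leap_store` snapshot.
#' @export
leap_as_of <- function(store, time) {
  t <- if (inherits(time, "POSIXt")) as.numeric(time) else as.numeric(time)
  recs <- Filter(function(r) r$ts <= t, .leap_records(store))
  snap <- .leap_replay(recs, actor = store$actor,
                       created_at = store$created_at)
  snap$readonly <- TRUE
  snap
}

#' History of one entity
#'
#' All change records touching the entity's own row, its facts, its links
#' (either endpoint), and -- because inherited values change an entity's
#' resolved set -- `UPDATE`/`DELETE` records of pairs referenced by facts of
#' any entity reachable from it through links (itself included). Pair
#' insertions are vocabulary growth, not entity changes, and are excluded.
#'
#' @param store A `leap_store`.
#' @param entity Entity (record, id, or unique label). May refer to a
#'   deleted entity by id.
#' @return A `data.frame` in the format of [leap_changes()], in seq order.
#' @export
leap_entity_history <- function(store, entity) {
  if (is.list(entity) && !is.null(entity$id)) {
    id <- as.integer(entity$id)
  } else if (is.numeric(entity)) {
    id <- as.integer(entity)
  } else {
    id <- .as_entity_id(store, entity)
  }
  ch <- leap_changes(store)
  img <- function(i) ch$new[[i]] %||% ch$old[[i]]
  touches_entity <- ch$table == "entity" & ch$row_id == id
  touches_fact <- ch$table == "fact" &
    vapply(seq_len(nrow(ch)), function(i) {
      ch$table[[i]] == "fact" && identical(img(i)$entity_id, id)
    }, logical(1))
  touches_link <- ch$table == "link" &
    vapply(seq_len(nrow(ch)), function(i) {
      ch$table[[i]] == "link" &&
        (identical(img(i)$source_id, id) || identical(img(i)$target_id, id))
    }, logical(1))
  # pairs referenced (now or historically) by facts of entities reachable
  # from this one, links followed forward
  scope <- c(id, .reachable(store, id))
  fact_recs <- ch[ch$table == "fact", , drop = FALSE]
  pair_ids <- unique(unlist(lapply(seq_len(nrow(fact_recs)), function(i) {
    im <- fact_recs$new[[i]] %||% fact_recs$old[[i]]
    if (im$entity_id %in% scope) im$pair_id else NULL
  })))
  touches_pair <- ch$table == "pair" & ch$op %in% c("UPDATE", "DELETE") &
    ch$row_id %in% pair_ids
  out <- ch[touches_entity | touches_fact | touches_link | touches_pair, ,
            drop = FALSE]
  out[order(out$seq), , drop = FALSE]
}
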