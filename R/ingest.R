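# Readers for classification tables and denormalized mapping sheets, and
# the dynamic-pivot exporter. Delimited text is CSV (double-quote quoting,
# mandatory header) with TSV accepted; values round-trip verbatim.

#' The seven GDC diagnosis attributes
#'
#' The data elements required per sample mapping: primary diagnosis, tissue
#' or organ of origin, tumor grade, morphology, site of resection or biopsy,
#' primary site, and disease type (snake_case, as in the GDC dictionary).
#'
#' @return A character vector of length 7.
#' @export
leap_gdc_diagnosis_attributes <- function() {
  c("primary_diagnosis", "tissue_or_organ_of_origin", "tumor_grade",
    "morphology", "site_of_resection_or_biopsy", "primary_site",
    "disease_type")
}

#' The sample-type vocabulary
#'
#' Each classification code is mapped once per sample type.
#'
#' @return `c("primary", "metastasis", "unspecified")`.
#' @export
leap_sample_types <- function() c("primary", "metastasis", "unspecified")

# ---- lossless delimited text --------------------------------------------

#' Read / write delimited text tables
#'
#' Every cell is kept as UTF-8 character data (no type guessing, no
#' leading-zero loss); embedded delimiters, quotes and newlines are
#' double-quote escaped; CRLF and LF line endings parse identically; a
#' header row is mandatory. `write` then `read` is lossless for arbitrary
#' text. Ragged rows are rejected with the offending line reported.
#'
#' @param path File path. Extension `.tsv` selects tab separation, anything
#'   else comma; override with `sep`.
#' @param table A `data.frame` of character columns (coerced).
#' @param sep Field separator, `","` or `"\t"`.
#' @return `leap_read_table()` returns a `data.frame` of character columns;
#'   `leap_write_table()` returns the path invisibly.
#' @export
leap_read_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                      quote = "\"", fill = FALSE, na.strings = character(0),
                      check.names = FALSE, comment.char = "",
                      fileEncoding = "UTF-8", stringsAsFactors = FALSE),
    warning = function(w) {
      stop(sprintf("malformed table '%s': %s", path, conditionMessage(w)),
           call. = FALSE)
    },
    error = function(e) {
      stop(sprintf("cannot read table '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  for (j in seq_along(df)) df[[j]] <- enc2utf8(df[[j]])
  df
}

#' @rdname leap_read_table
#' @export
leap_write_table <- function(table, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  con <- file(path, open = "wb")  # binary keeps LF endings on any platform
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = sep, row.names = FALSE, col.names = TRUE,
                     qmethod = "double", quote = TRUE, na = "",
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

# ---- classification tables ----------------------------------------------

#' Construct a classification table
#'
#' A versioned snapshot of one classification system (OncoTree-style):
#' one record per code with its name, main type, tissue (site), and an
#' optional parent code forming a tree.
#'
#' @param system_name System name, e.g. `"oncotree"`.
#' @param version_label Version label, e.g. `"oncotree_2017_06_21"`.
#' @param records A `data.frame` with columns `code`, `name`, `main_type`,
#'   `tissue`, and optionally `parent_code` (empty/NA for roots).
#' @return An object of class `leap_classification`.
#' @export
leap_classification <- function(system_name, version_label, records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("code", "name", "main_type", "tissue")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("classification records lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"parent_code" %in% names(records)) records$parent_code <- ""
  records$parent_code[is.na(records$parent_code)] <- ""
  for (col in c(required, "parent_code")) {
    records[[col]] <- as.character(records[[col]])
  }
  dup <- records$code[duplicated(records$code)]
  if (length(dup) > 0L) {
    stop("duplicate code(s) within version: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(setdiff(records$parent_code, ""), records$code)
  if (length(orphan) > 0L) {
    stop("parent_code(s) not present in version: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(system = system_name, version = version_label,
                 records = records[, c("code", "name", "main_type", "tissue",
                                       "parent_code")]),
            class = "leap_classification")
}

#' @export
print.leap_classification <- function(x, ...) {
  cat(sprintf("<leap_classification> %s %s: %d codes, %d tissues\n",
              x$system, x$version, nrow(x$records),
              length(unique(x$records$tissue))))
  invisible(x)
}

#' Read / write a classification table file
#'
#' @param path Delimited text file with columns `code`, `name`, `main_type`,
#'   `tissue`, optionally `parent_code`.
#' @param system_name,version_label Passed to [leap_classification()].
#' @param classification A `leap_classification` to write.
#' @param sep See [leap_read_table()].
#' @return A `leap_classification` / the path, invisibly.
#' @export
leap_read_classification <- function(path, system_name, version_label,
                                     sep = NULL) {
  leap_classification(system_name, version_label, leap_read_table(path, sep))
}

#' @rdname leap_read_classification
#' @export
leap_write_classification <- function(classification, path, sep = NULL) {
  leap_write_table(classification$records, path, sep)
}

.version_marker_type <- "classification version"

#' Load a classification version into a store
#'
#' Creates one entity per code under the entity type `"<system> code"`,
#' direct facts for `tissue`, `main_type` and `name`, and a link from each
#' child to its parent entity (role `"parent"`). A marker entity records the
#' loaded version; loading the same version label twice is rejected. The
#' import is transactional.
#'
#' @param store A writable `leap_store`.
#' @param classification A `leap_classification`.
#' @return A list: `entities_created`, `facts_created`, `links_created`.
#' @export
leap_load_classification <- function(store, classification) {
  stopifnot(inherits(classification, "leap_classification"))
  marker <- paste0(classification$system, ":", classification$version)
  et <- store$tables$entity_type
  midx <- .tbl_which(et, "name", .version_marker_type)
  if (length(midx) == 1L) {
    mid <- .tbl_col(et, "id")[midx]
    labels <- leap_entities(store)
    if (marker %in% labels$label[labels$entity_type_id == mid]) {
      stop(sprintf("version '%s' is already loaded", classification$version),
           call. = FALSE)
    }
  }
  .leap_transaction(store, function(st) {
    vt <- .ensure_entity_type(st, .version_marker_type)
    leap_add_entity(st, vt, marker)
    ct <- .ensure_entity_type(st, paste(classification$system, "code"))
    for (a in c("tissue", "main_type", "name")) .ensure_attribute(st, a)
    rec <- classification$records
    n_facts <- 0L
    ents <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec))) {
      ents[[i]] <- leap_add_entity(st, ct, rec$code[[i]])
      for (a in c("tissue", "main_type", "name")) {
        v <- rec[[a]][[i]]
        if (nzchar(v)) {
          leap_set_fact(st, ents[[i]], a, v)
          n_facts <- n_facts + 1L
        }
      }
    }
    n_links <- 0L
    for (i in seq_len(nrow(rec))) {
      p <- rec$parent_code[[i]]
      if (nzchar(p)) {
        parent <- ents[[match(p, rec$code)]]
        leap_add_link(st, ents[[i]], parent, role = "parent")
        n_links <- n_links + 1L
      }
    }
    list(entities_created = nrow(rec), facts_created = n_facts,
         links_created = n_links)
  })
}

# ---- mapping sheets ------------------------------------------------------

#' The default link specification for GDC diagnosis mapping sheets
#'
#' A link spec declares which sheet columns induce links to which entity
#' types, and which columns ride along as facts on the linked (target)
#' entity instead of being copied onto each mapping row. With the shipped
#' default, a mapping entity stores only its identifying facts
#' (`oncotree_code`, `sample_type`) directly; the OncoTree descriptive
#' fields live on the code entity, and the seven GDC diagnosis fields live
#' on the morphology and topography entities, so a correction to a shared
#' code cascades through the links rather than being edited row by row.
#'
#' @return A named list of rules, each
#'   `list(column =, entity_type =, carries =, create_missing = TRUE)`.
#' @export
leap_default_link_spec <- function() {
  list(
    oncotree = list(column = "oncotree_code", entity_type = "oncotree code",
                    carries = c("tissue", "main_type", "name"),
                    create_missing = TRUE),
    morphology = list(column = "morphology", entity_type = "GDC morphology",
                      carries = c("morphology", "primary_diagnosis",
                                  "tumor_grade", "disease_type"),
                      create_missing = TRUE),
    topography = list(column = "tissue_or_organ_of_origin",
                      entity_type = "GDC topography",
                      carries = c("tissue_or_organ_of_origin", "primary_site",
                                  "site_of_resection_or_biopsy"),
                      create_missing = TRUE)
  )
}

#' Read a link specification from JSON or YAML
#'
#' @param path A `.json` or `.yaml`/`.yml` file holding the structure
#'   returned by [leap_default_link_spec()].
#' @return A link spec list.
#' @export
leap_read_link_spec <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  for (rule in spec) {
    if (is.null(rule$column) || is.null(rule$entity_type)) {
      stop("each link-spec rule needs `column` and `entity_type`",
           call. = FALSE)
    }
  }
  spec
}

#' Load a denormalized mapping sheet into a store
#'
#' Each sheet row becomes one mapping entity (label `"<code>|<sample_type>"`)
#' of `entity_type`. Columns named by the link spec induce links: the cell
#' value is the label of the target entity, which is created on first sight
#' (when the rule allows) with the rule's `carries` columns as its facts.
#' All remaining columns (minus `label`) become direct facts on the mapping
#' entity. Descriptive values are therefore inherited through links, never
#' copied per row. The import is all-or-nothing: any row error (unknown
#' sample type, duplicate mapping, carried values contradicting an already
#' loaded target entity) rolls the whole import back.
#'
#' @param store A writable `leap_store`.
#' @param sheet A `data.frame` (e.g. from [leap_read_table()]) with columns
#'   `oncotree_code` and `sample_type`, plus descriptive columns.
#' @param link_spec See [leap_default_link_spec()].
#' @param entity_type Entity type for mapping rows.
#' @return A list: `mappings_created`, `facts_created`, `links_created`,
#'   `targets_created`.
#' @export
leap_load_mapping_sheet <- function(store, sheet,
                                    link_spec = leap_default_link_spec(),
                                    entity_type = "GENIE mapping") {
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  if (!all(c("oncotree_code", "sample_type") %in% names(sheet))) {
    stop("mapping sheet needs columns `oncotree_code` and `sample_type`",
         call. = FALSE)
  }
  bad <- setdiff(unique(sheet$sample_type), leap_sample_types())
  if (length(bad) > 0L) {
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  carried <- unique(unlist(lapply(link_spec, `[[`, "carries")))
  link_cols <- vapply(link_spec, `[[`, "", "column")
  direct_cols <- setdiff(names(sheet), c(carried, "label"))
  labels <- paste0(sheet$oncotree_code, "|", sheet$sample_type)
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L) {
    stop("duplicate (code, sample_type) row(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  .leap_transaction(store, function(st) {
    mt <- .ensure_entity_type(st, entity_type)
    for (a in direct_cols) .ensure_attribute(st, a)
    for (rule in link_spec) for (a in rule$carries) .ensure_attribute(st, a)
    rule_type <- lapply(link_spec, function(rule)
      .ensure_entity_type(st, rule$entity_type))
    n_facts <- 0L
    n_links <- 0L
    n_targets <- 0L
    errors <- character(0)
    # target entities and their carried facts, cached per (rule, label)
    cache <- new.env(parent = emptyenv())
    get_target <- function(rn, target_label) {
      key <- paste0(rn, "\r", target_label)
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      tt <- rule_type[[rn]]
      ent_tab <- st$tables$entity
      tidx <- intersect(.tbl_which(ent_tab, "label", target_label),
                        .tbl_which(ent_tab, "entity_type_id", tt$id))
      if (length(tidx) == 0L) {
        if (!isTRUE(link_spec[[rn]]$create_missing %||% TRUE)) {
          return(NULL)
        }
        target <- leap_add_entity(st, tt, target_label)
        n_targets <<- n_targets + 1L
        facts <- character(0)
      } else {
        target <- .tbl_row(ent_tab, tidx, .leap_tables$entity)
        known <- .direct_facts(st, target$id)
        facts <- known$value
        names(facts) <- known$attribute
      }
      entry <- list2env(list(ent = target, facts = facts),
                        parent = emptyenv())
      cache[[key]] <- entry
      entry
    }
    carried_cols <- lapply(link_spec, function(rule)
      intersect(rule$carries, names(sheet)))
    for (i in seq_len(nrow(sheet))) {
      me <- leap_add_entity(st, mt, labels[[i]])
      for (a in direct_cols) {
        v <- sheet[[a]][[i]]
        if (nzchar(v)) {
          leap_set_fact(st, me, a, v)
          n_facts <- n_facts + 1L
        }
      }
      for (rn in names(link_spec)) {
        rule <- link_spec[[rn]]
        target_label <- sheet[[rule$column]][[i]]
        if (!nzchar(target_label)) next
        entry <- get_target(rn, target_label)
        if (is.null(entry)) {
          errors <- c(errors, sprintf(
            "row %d: unknown %s '%s'", i, rule$entity_type, target_label))
          next
        }
        for (a in carried_cols[[rn]]) {
          v <- sheet[[a]][[i]]
          if (!nzchar(v)) next
          have <- if (a %in% names(entry$facts)) entry$facts[[a]] else NULL
          if (is.null(have)) {
            leap_set_fact(st, entry$ent, a, v)
            entry$facts[[a]] <- v
          } else if (!identical(have, v)) {
            errors <- c(errors, sprintf(
              "row %d: %s '%s' already carries %s = '%s', sheet says '%s'",
              i, rule$entity_type, target_label, a, have, v))
          }
        }
        leap_add_link(st, me, entry$ent, role = rn)
        n_links <- n_links + 1L
      }
    }
    if (length(errors) > 0L) {
      stop("mapping sheet rejected (import rolled back):\n  ",
           paste(errors, collapse = "\n  "), call. = FALSE)
    }
    list(mappings_created = nrow(sheet), facts_created = n_facts,
         links_created = n_links, targets_created = n_targets)
  })
}

# ---- dynamic pivot export ------------------------------------------------

#' Export entities of one type as a denormalized table
#'
#' The dynamic pivot: columns are discovered from the data -- the entity
#' label plus the union of all attribute names appearing in any resolved
#' (inheritance-inclusive) set of the type, in first-seen order unless
#' `attribute_order` is given. No column names are hard-coded. Missing
#' values are empty strings. Any entity whose resolution raises an
#' inheritance conflict aborts the export with the offending entities
#' listed.
#'
#' @param store A `leap_store`.
#' @param entity_type Entity type name to pivot.
#' @param attribute_order Optional explicit column order (attribute names).
#' @param exclude_attributes Attributes to drop from the export; defaults to
#'   the reserved manual-annotation attribute, which is workflow metadata
#'   rather than mapping content.
#' @return A `data.frame`: column `label` then one column per attribute,
#'   one row per entity, ordered by label.
#' @export
leap_export_denormalized <- function(store, entity_type,
                                     attribute_order = NULL,
                                     exclude_attributes = leap_annotation_attribute()) {
  .as_entity_type_id(store, entity_type)  # validate the type exists
  resolved <- .resolved_of_type(store, entity_type, capture_conflicts = TRUE)
  conflicts <- unlist(lapply(resolved, function(r) {
    if (inherits(r, "leap_conflict_error")) {
      sprintf("%s (%s)", r$entity, conditionMessage(r))
    }
  }))
  if (length(conflicts) > 0L) {
    stop("export aborted; unresolvable conflicts for entities:\n  ",
         paste(conflicts, collapse = "\n  "), call. = FALSE)
  }
  cols <- character(0)
  for (r in resolved) cols <- union(cols, names(r$entries))
  cols <- setdiff(cols, exclude_attributes)
  if (!is.null(attribute_order)) {
    unknown <- setdiff(attribute_order, cols)
    if (length(unknown) > 0L) {
      stop("attribute_order names absent from the data: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cols <- c(attribute_order, setdiff(cols, attribute_order))
  }
  out <- c(list(label = vapply(resolved, `[[`, "", "label")),
           lapply(cols, function(a) {
             vapply(resolved, function(r) {
               e <- r$entries[[a]]
               if (is.null(e)) "" else e$value
             }, "")
           }))
  names(out) <- c("label", cols)
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
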