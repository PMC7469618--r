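# Data-dictionary validation: detect and classify mapping defects.
# Categories: UNKNOWN_TERM (value not in the dictionary at all),
# CAPITALIZATION_MISMATCH (only a case-folded match exists),
# DEPENDENT_FIELD_MISMATCH (both values allowable but their combination
# violates a dependency rule), ANNOTATED_INACCURATE (human-entered
# annotation of a semantically wrong mapping; never auto-detected).

.finding_categories <- c("UNKNOWN_TERM", "CAPITALIZATION_MISMATCH",
                         "DEPENDENT_FIELD_MISMATCH", "ANNOTATED_INACCURATE")

#' The reserved manual-annotation attribute
#'
#' Inaccurate mappings (a wrong morphology or tissue link that is
#' syntactically valid) require expert judgment; they are recorded as
#' free-text facts on this attribute and surface in validation reports as
#' `ANNOTATED_INACCURATE`.
#'
#' @return The attribute name, `"flagged_inaccurate"`.
#' @export
leap_annotation_attribute <- function() "flagged_inaccurate"

#' Annotate a mapping as inaccurate
#'
#' @param store A writable `leap_store`.
#' @param entity Entity (record, id, or unique label).
#' @param note Free-text reason.
#' @return The fact record, invisibly.
#' @export
leap_annotate_inaccurate <- function(store, entity, note) {
  .ensure_attribute(store, leap_annotation_attribute())
  invisible(leap_set_fact(store, entity, leap_annotation_attribute(), note))
}

#' Construct a data dictionary
#'
#' @param attributes Named list: attribute name -> character vector of
#'   allowable values (nonempty).
#' @param dependencies Optional list of dependency rules, each
#'   `list(key =, dependent =, pairs =)` where `pairs` is a list of
#'   `c(key_value, dependent_value)` combinations that are allowed. Every
#'   key value must be allowable for the key attribute.
#' @return An object of class `leap_dictionary`.
#' @export
leap_dictionary <- function(attributes, dependencies = list()) {
  if (length(attributes) == 0L || is.null(names(attributes))) {
    stop("`attributes` must be a named list of allowable-value vectors",
         call. = FALSE)
  }
  attributes <- lapply(attributes, as.character)
  empty <- names(attributes)[vapply(attributes, length, 0L) == 0L]
  if (length(empty) > 0L) {
    stop("empty allowable-value set for: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  dependencies <- lapply(dependencies, function(d) {
    if (is.null(d$key) || is.null(d$dependent) || is.null(d$pairs)) {
      stop("each dependency rule needs `key`, `dependent`, `pairs`",
           call. = FALSE)
    }
    if (!d$key %in% names(attributes) || !d$dependent %in% names(attributes)) {
      stop(sprintf("dependency rule %s -> %s references undeclared attributes",
                   d$key, d$dependent), call. = FALSE)
    }
    pairs <- do.call(rbind, lapply(d$pairs, function(p) {
      as.character(p[1:2])
    }))
    bad <- setdiff(pairs[, 1L], attributes[[d$key]])
    if (length(bad) > 0L) {
      stop(sprintf("rule %s -> %s lists key value(s) not allowable: %s",
                   d$key, d$dependent, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    list(key = d$key, dependent = d$dependent, pairs = pairs)
  })
  structure(list(attributes = attributes, dependencies = dependencies),
            class = "leap_dictionary")
}

#' @export
print.leap_dictionary <- function(x, ...) {
  cat(sprintf("<leap_dictionary> %d attributes, %d dependency rule(s)\n",
              length(x$attributes), length(x$dependencies)))
  invisible(x)
}

#' Read / write a data dictionary (JSON)
#'
#' Format: `{"attributes": {name: [values...]}, "dependencies":
#' [{"key":..., "dependent":..., "pairs": [[k, v], ...]}]}`.
#'
#' @param path JSON file path.
#' @param dictionary A `leap_dictionary`.
#' @return A `leap_dictionary` / the path, invisibly.
#' @export
leap_read_dictionary <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  leap_dictionary(raw$attributes, raw$dependencies %||% list())
}

#' @rdname leap_read_dictionary
#' @export
leap_write_dictionary <- function(dictionary, path) {
  payload <- list(
    attributes = dictionary$attributes,
    dependencies = lapply(dictionary$dependencies, function(d) {
      list(key = d$key, dependent = d$dependent,
           pairs = lapply(seq_len(nrow(d$pairs)),
                          function(i) unname(d$pairs[i, ])))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# comparison key: trim outer whitespace, Unicode-lowercase
.fold <- function(x) tolower(trimws(x))

.empty_findings <- function() {
  data.frame(entity = character(0), attribute = character(0),
             observed = character(0), category = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

.order_findings <- function(f) {
  f[order(f$entity, f$attribute, method = "radix"), , drop = FALSE]
}

# resolved sets for every entity of a type, sorted by label; with
# `capture_conflicts` a conflict condition takes the entity's place
.resolved_of_type <- function(store, entity_type, capture_conflicts = FALSE) {
  type_id <- .as_entity_type_id(store, entity_type)
  ent <- leap_entities(store)
  ent <- ent[ent$entity_type_id == type_id, , drop = FALSE]
  ent <- ent[order(ent$label, method = "radix"), , drop = FALSE]
  ctx <- .resolve_ctx(store)
  lapply(seq_len(nrow(ent)), function(i) {
    if (capture_conflicts) {
      tryCatch(.resolve_one(ctx, ent$id[[i]]),
               leap_conflict_error = function(e) e)
    } else {
      .resolve_one(ctx, ent$id[[i]])
    }
  })
}

#' Check resolved values against the dictionary's allowable values
#'
#' For every resolved (entity, attribute, value) of the given type whose
#' attribute the dictionary declares: an exact allowable value passes;
#' a value matching an allowable value only after trimming and case folding
#' is a `CAPITALIZATION_MISMATCH` (the detail names the correct form);
#' anything else is an `UNKNOWN_TERM` (the detail suggests the nearest
#' allowable value by edit distance). Comparison in the core store is exact;
#' only this check case-folds. Attributes present in the store but absent
#' from the dictionary are listed in the `unchecked_attributes` attribute of
#' the result, not reported as findings. The check is read-only.
#'
#' @param store A `leap_store`.
#' @param dictionary A `leap_dictionary`.
#' @param entity_type Entity type name to check.
#' @return A findings `data.frame` (`entity`, `attribute`, `observed`,
#'   `category`, `detail`), ordered by entity label then attribute.
#' @export
leap_check_allowable_values <- function(store, dictionary, entity_type) {
  stopifnot(inherits(dictionary, "leap_dictionary"))
  .check_values(.resolved_of_type(store, entity_type), dictionary)
}

.check_values <- function(resolved, dictionary) {
  declared <- names(dictionary$attributes)
  trimmed <- lapply(dictionary$attributes, trimws)
  folded <- lapply(trimmed, tolower)
  rows <- list()
  unchecked <- character(0)
  for (r in resolved) {
    for (a in names(r$entries)) {
      if (a == leap_annotation_attribute()) next
      if (!a %in% declared) {
        unchecked <- union(unchecked, a)
        next
      }
      v <- r$entries[[a]]$value
      allowed <- dictionary$attributes[[a]]
      if (trimws(v) %in% trimmed[[a]]) next
      fold_hit <- which(folded[[a]] == .fold(v))
      if (length(fold_hit) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity = r$label, attribute = a, observed = v,
          category = "CAPITALIZATION_MISMATCH",
          detail = sprintf("dictionary form is '%s'", allowed[[fold_hit[1L]]]),
          stringsAsFactors = FALSE)
      } else {
        nearest <- allowed[[which.min(utils::adist(v, allowed))]]
        rows[[length(rows) + 1L]] <- data.frame(
          entity = r$label, attribute = a, observed = v,
          category = "UNKNOWN_TERM",
          detail = sprintf("not in dictionary; nearest allowable value is '%s'",
                           nearest),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) {
    .order_findings(do.call(rbind, rows))
  } else {
    .empty_findings()
  }
  attr(out, "unchecked_attributes") <- sort(unchecked)
  out
}

#' Check dependent-field consistency
#'
#' For each dependency rule and each entity of the type resolving both the
#' key and the dependent attribute to exact allowable values: if the
#' observed (key value, dependent value) combination is not among the
#' rule's allowed pairs, a `DEPENDENT_FIELD_MISMATCH` is reported on the
#' dependent attribute, citing the rule and the dependent values expected
#' for that key. Pairs where either side fails the allowable-value check
#' are not assessed here (they already carry a value-level finding, keeping
#' categories mutually exclusive per entity and attribute). Entities
#' resolving only one side are listed in the `incomplete_pairs` attribute
#' of the result. Read-only.
#'
#' @inheritParams leap_check_allowable_values
#' @return A findings `data.frame`, ordered by entity label then attribute.
#' @export
leap_check_dependent_fields <- function(store, dictionary, entity_type) {
  stopifnot(inherits(dictionary, "leap_dictionary"))
  .check_deps(.resolved_of_type(store, entity_type), dictionary)
}

.check_deps <- function(resolved, dictionary) {
  rows <- list()
  incomplete <- character(0)
  for (rule in dictionary$dependencies) {
    key_allowed <- trimws(dictionary$attributes[[rule$key]])
    dep_allowed <- trimws(dictionary$attributes[[rule$dependent]])
    for (r in resolved) {
      k <- r$entries[[rule$key]]
      d <- r$entries[[rule$dependent]]
      if (is.null(k) && is.null(d)) next
      if (is.null(k) || is.null(d)) {
        incomplete <- union(incomplete, sprintf(
          "%s: %s/%s", r$label, rule$key, rule$dependent))
        next
      }
      kv <- trimws(k$value)
      dv <- trimws(d$value)
      if (!(kv %in% key_allowed) || !(dv %in% dep_allowed)) {
        next  # value-level defect; reported by the allowable-value check
      }
      hit <- rule$pairs[, 1L] == kv & rule$pairs[, 2L] == dv
      if (!any(hit)) {
        expected <- rule$pairs[rule$pairs[, 1L] == kv, 2L]
        rows[[length(rows) + 1L]] <- data.frame(
          entity = r$label, attribute = rule$dependent, observed = d$value,
          category = "DEPENDENT_FIELD_MISMATCH",
          detail = sprintf(
            "rule %s -> %s: for %s = '%s' expected %s",
            rule$key, rule$dependent, rule$key, kv,
            if (length(expected) > 0L) {
              paste(sprintf("'%s'", expected), collapse = " or ")
            } else "no dependent value (key has no allowed pairs)"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) {
    .order_findings(do.call(rbind, rows))
  } else {
    .empty_findings()
  }
  attr(out, "incomplete_pairs") <- sort(incomplete)
  out
}

#' Validate a store against a data dictionary
#'
#' Union of [leap_check_allowable_values()], [leap_check_dependent_fields()]
#' and the manual `ANNOTATED_INACCURATE` annotations, with per-category
#' counts and the deduplicated set of entities needing remediation.
#' Validation never mutates the store or its history.
#'
#' @inheritParams leap_check_allowable_values
#' @return An object of class `leap_validation_report`: list with
#'   `findings` (data frame ordered by entity then attribute), `counts`
#'   (named integer vector over all four categories),
#'   `entities_needing_remediation` (character), and `metadata`
#'   (`unchecked_attributes`, `incomplete_pairs`).
#' @export
leap_validate <- function(store, dictionary, entity_type) {
  stopifnot(inherits(dictionary, "leap_dictionary"))
  resolved <- .resolved_of_type(store, entity_type)
  values <- .check_values(resolved, dictionary)
  deps <- .check_deps(resolved, dictionary)
  ann_rows <- list()
  for (r in resolved) {
    e <- r$entries[[leap_annotation_attribute()]]
    if (!is.null(e)) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        entity = r$label, attribute = leap_annotation_attribute(),
        observed = e$value, category = "ANNOTATED_INACCURATE",
        detail = e$value, stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(ann_rows) > 0L) do.call(rbind, ann_rows) else .empty_findings()
  meta_unchecked <- attr(values, "unchecked_attributes")
  meta_incomplete <- attr(deps, "incomplete_pairs")
  attr(values, "unchecked_attributes") <- NULL
  attr(deps, "incomplete_pairs") <- NULL
  findings <- .order_findings(rbind(values, deps, ann))
  rownames(findings) <- NULL
  counts <- vapply(.finding_categories,
                   function(cat) sum(findings$category == cat), 0L)
  structure(list(
    findings = findings,
    counts = counts,
    entities_needing_remediation = sort(unique(findings$entity)),
    metadata = list(
      unchecked_attributes = meta_unchecked,
      incomplete_pairs = meta_incomplete)),
    class = "leap_validation_report")
}

#' @export
print.leap_validation_report <- function(x, ...) {
  cat(sprintf("<leap_validation_report> %d finding(s), %d entit%s needing remediation\n",
              nrow(x$findings), length(x$entities_needing_remediation),
              if (length(x$entities_needing_remediation) == 1L) "y" else "ies"))
  for (cat_ in names(x$counts)) {
    if (x$counts[[cat_]] > 0L) cat(sprintf("  %s: %d\n", cat_, x$counts[[cat_]]))
  }
  if (length(x$metadata$unchecked_attributes) > 0L) {
    cat("  unchecked attributes:",
        paste(x$metadata$unchecked_attributes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation report to JSON or CSV
#'
#' @param report A `leap_validation_report`.
#' @param path Output path; `.json` writes the full report, anything else a
#'   findings table in delimited text.
#' @return The path, invisibly.
#' @export
leap_write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      findings = report$findings,
      counts = as.list(report$counts),
      entities_needing_remediation = report$entities_needing_remediation,
      metadata = report$metadata), path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  } else {
    leap_write_table(report$findings, path)
  }
  invisible(path)
}
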