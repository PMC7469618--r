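# Version diffing between two releases of a classification system, and
# flagging of mappings that need re-review after a release.

#' Diff two versions of a classification system
#'
#' Codes are the identity key across versions (a code renaming itself shows
#' up as remove + add). Same-code differences are classified: `renamed`
#' (name changed), `reparented` (parent changed), `refielded` (tissue or
#' main type changed). A code may appear in several of the change sets but
#' never in both `added` and `removed`. The diff is antisymmetric: swapping
#' the arguments swaps added/removed and inverts every old/new column.
#'
#' @param old,new `leap_classification` objects.
#' @return An object of class `leap_version_diff`: list with `added`,
#'   `removed` (character code vectors), `renamed` (`code`, `old_name`,
#'   `new_name`), `reparented` (`code`, `old_parent`, `new_parent`),
#'   `refielded` (`code`, `field`, `old`, `new`), plus `old_version` /
#'   `new_version` labels.
#' @export
leap_diff_classifications <- function(old, new) {
  stopifnot(inherits(old, "leap_classification"),
            inherits(new, "leap_classification"))
  o <- old$records
  n <- new$records
  added <- sort(setdiff(n$code, o$code))
  removed <- sort(setdiff(o$code, n$code))
  common <- sort(intersect(o$code, n$code))
  oi <- match(common, o$code)
  ni <- match(common, n$code)
  ren <- common[o$name[oi] != n$name[ni]]
  renamed <- data.frame(code = ren,
                        old_name = o$name[match(ren, o$code)],
                        new_name = n$name[match(ren, n$code)],
                        stringsAsFactors = FALSE)
  rep_ <- common[o$parent_code[oi] != n$parent_code[ni]]
  reparented <- data.frame(code = rep_,
                           old_parent = o$parent_code[match(rep_, o$code)],
                           new_parent = n$parent_code[match(rep_, n$code)],
                           stringsAsFactors = FALSE)
  ref_rows <- list()
  for (field in c("tissue", "main_type")) {
    chg <- common[o[[field]][oi] != n[[field]][ni]]
    if (length(chg) > 0L) {
      ref_rows[[field]] <- data.frame(
        code = chg, field = field,
        old = o[[field]][match(chg, o$code)],
        new = n[[field]][match(chg, n$code)],
        stringsAsFactors = FALSE)
    }
  }
  refielded <- if (length(ref_rows) > 0L) {
    out <- do.call(rbind, ref_rows)
    rownames(out) <- NULL
    out[order(out$code, out$field, method = "radix"), , drop = FALSE]
  } else {
    data.frame(code = character(0), field = character(0),
               old = character(0), new = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(added = added, removed = removed, renamed = renamed,
                 reparented = reparented, refielded = refielded,
                 old_version = old$version, new_version = new$version),
            class = "leap_version_diff")
}

#' Codes changed in place by a diff
#'
#' @param diff A `leap_version_diff`.
#' @return Sorted character vector of codes that were renamed, reparented,
#'   or refielded.
#' @export
leap_changed_codes <- function(diff) {
  sort(unique(c(diff$renamed$code, diff$reparented$code,
                diff$refielded$code)))
}

#' @export
print.leap_version_diff <- function(x, ...) {
  cat(sprintf("<leap_version_diff> %s -> %s\n", x$old_version, x$new_version))
  cat(sprintf("  added %d, removed %d, renamed %d, reparented %d, refielded %d\n",
              length(x$added), length(x$removed), nrow(x$renamed),
              nrow(x$reparented), nrow(x$refielded)))
  invisible(x)
}

# round half away from zero to integer (printed summaries use whole percent)
.round_half_up <- function(x) floor(x + 0.5)

#' Summarize a version diff by a grouping field
#'
#' Groups the diff's additions by the new version's value of `group_field`
#' (e.g. `tissue`) and reports, per group, the added / removed / changed
#' code counts and each group's share of total additions as a whole
#' percent (round-half-up). Removed codes are grouped by the old version's
#' field value when `old` is supplied, otherwise counted under `""`.
#'
#' @param diff A `leap_version_diff`.
#' @param new The new `leap_classification` (source of group values).
#' @param group_field One of `"tissue"`, `"main_type"`, `"name"`.
#' @param old Optional old `leap_classification` for grouping removals.
#' @return An object of class `leap_diff_summary`: a `data.frame` with
#'   columns `group`, `added`, `removed`, `changed`, `pct_of_additions`,
#'   sorted by `added` descending; total additions in attribute
#'   `total_added`.
#' @export
leap_summarize_diff <- function(diff, new, group_field = "tissue",
                                old = NULL) {
  stopifnot(inherits(diff, "leap_version_diff"),
            inherits(new, "leap_classification"))
  if (!group_field %in% c("tissue", "main_type", "name")) {
    stop(sprintf("unknown classification field '%s'", group_field),
         call. = FALSE)
  }
  n <- new$records
  add_groups <- n[[group_field]][match(diff$added, n$code)]
  rem_groups <- if (!is.null(old)) {
    old$records[[group_field]][match(diff$removed, old$records$code)]
  } else {
    rep("", length(diff$removed))
  }
  changed <- leap_changed_codes(diff)
  changed <- changed[changed %in% n$code]
  chg_groups <- n[[group_field]][match(changed, n$code)]
  groups <- sort(unique(c(add_groups, rem_groups[nzchar(rem_groups)],
                          chg_groups)))
  total_added <- length(diff$added)
  out <- data.frame(
    group = groups,
    added = vapply(groups, function(g) sum(add_groups == g), 0L),
    removed = vapply(groups, function(g) sum(rem_groups == g), 0L),
    changed = vapply(groups, function(g) sum(chg_groups == g), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out$pct_of_additions <- if (total_added > 0L) {
    as.integer(.round_half_up(100 * out$added / total_added))
  } else {
    rep(0L, nrow(out))
  }
  out <- out[order(-out$added, out$group, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_added") <- total_added
  attr(out, "group_field") <- group_field
  class(out) <- c("leap_diff_summary", "data.frame")
  out
}

#' Flag mappings needing re-review after a classification release
#'
#' Every mapping entity whose code fact refers to a removed, renamed,
#' reparented or refielded code is flagged for human re-review; added codes
#' with no mapping yet are listed separately as coverage gaps. No
#' re-mapping is attempted.
#'
#' @param store A `leap_store` containing mapping entities.
#' @param diff A `leap_version_diff`.
#' @param entity_type Mapping entity type name.
#' @param code_attribute Attribute on mapping entities holding the code.
#' @return An object of class `leap_review_flags`: list with `flagged`
#'   (a `data.frame` of mapping `label`, `code`, `reason`) and
#'   `unmapped_added_codes` (character).
#' @export
leap_flag_for_review <- function(store, diff, entity_type = "GENIE mapping",
                                 code_attribute = "oncotree_code") {
  stopifnot(inherits(diff, "leap_version_diff"))
  resolved <- .resolved_of_type(store, entity_type)
  codes <- vapply(resolved, function(r) {
    e <- r$entries[[code_attribute]]
    if (is.null(e)) NA_character_ else e$value
  }, "")
  labels <- vapply(resolved, `[[`, "", "label")
  reason_of <- function(code) {
    reasons <- c(
      if (code %in% diff$removed) "removed",
      if (code %in% diff$renamed$code) "renamed",
      if (code %in% diff$reparented$code) "reparented",
      if (code %in% diff$refielded$code) "refielded")
    if (length(reasons) == 0L) NA_character_ else
      paste(reasons, collapse = "+")
  }
  reasons <- vapply(codes, function(cd) {
    if (is.na(cd)) NA_character_ else reason_of(cd)
  }, "")
  keep <- !is.na(reasons)
  flagged <- data.frame(label = labels[keep], code = codes[keep],
                        reason = reasons[keep], stringsAsFactors = FALSE)
  flagged <- flagged[order(flagged$label, method = "radix"), , drop = FALSE]
  rownames(flagged) <- NULL
  unmapped <- sort(setdiff(diff$added, codes[!is.na(codes)]))
  structure(list(flagged = flagged, unmapped_added_codes = unmapped),
            class = "leap_review_flags")
}

#' @export
print.leap_review_flags <- function(x, ...) {
  cat(sprintf("<leap_review_flags> %d mapping(s) to re-review, %d added code(s) unmapped\n",
              nrow(x$flagged), length(x$unmapped_added_codes)))
  invisible(x)
}
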