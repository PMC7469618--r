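# Deterministic synthetic fixtures: a toy OncoTree-like classification in
# two versions, a GDC-style data dictionary, a denormalized mapping sheet
# with seeded defects, and the exhaustive ground truth needed to score the
# validator and the version diff. Vocabularies are synthetic but shaped
# like the real ones (ICD-O-3 morphology "NNNN/E", topography "CNN.N").

.defect_categories <- c(capitalization = "CAPITALIZATION_MISMATCH",
                        unknown_term = "UNKNOWN_TERM",
                        dependent_mismatch = "DEPENDENT_FIELD_MISMATCH",
                        annotated_inaccurate = "ANNOTATED_INACCURATE")

#' Specify a synthetic fixture world
#'
#' Defaults emulate the GENIE-to-GDC study conditions: 286 codes mapped
#' once per sample type giving an 858-row, 13-column sheet, seven GDC
#' diagnosis attributes backed by shared morphology/topography entities,
#' and defect rates shaped like the observed error profile (capitalization
#' dominating the unknown-term class, a smaller dependent-field class, and
#' a reviewer-annotated inaccurate class on individual mappings).
#'
#' `capitalization`, `unknown_term` and `dependent_mismatch` rates are the
#' fraction of GDC vocabulary entities corrupted (at most one defect per
#' entity; the corruption reaches every mapping row sharing that entity);
#' `annotated_inaccurate` is the fraction of mapping rows annotated.
#'
#' @param seed Integer seed; same spec + seed gives byte-identical worlds.
#' @param n_codes Number of classification codes (>= 1).
#' @param tissues Tissue group labels for the classification tree.
#' @param sample_types Subset of [leap_sample_types()].
#' @param defect_rates Named numeric in `[0, 1]` over
#'   `capitalization`, `unknown_term`, `dependent_mismatch`,
#'   `annotated_inaccurate`.
#' @param n_morphology,n_topography Sizes of the shared GDC vocabularies.
#' @param version_edit_script Optional explicit edit list (see
#'   [leap_generate_world()] details); `NULL` generates a release-style
#'   script with additions concentrated in the myeloid and lymphoid groups.
#' @return An object of class `leap_fixture_spec`.
#' @export
leap_fixture_spec <- function(seed = 1L,
                              n_codes = 286L,
                              tissues = c("myeloid", "lymphoid", "breast",
                                          "lung", "bowel", "cns", "skin",
                                          "soft tissue", "ovary",
                                          "salivary gland"),
                              sample_types = leap_sample_types(),
                              defect_rates = c(capitalization = 0.07,
                                               unknown_term = 0.02,
                                               dependent_mismatch = 0.06,
                                               annotated_inaccurate = 0.11),
                              n_morphology = NULL,
                              n_topography = NULL,
                              version_edit_script = NULL) {
  n_codes <- as.integer(n_codes)
  if (is.na(n_codes) || n_codes < 1L) stop("n_codes must be >= 1", call. = FALSE)
  if (!all(sample_types %in% leap_sample_types())) {
    stop("sample_types must be drawn from ",
         paste(leap_sample_types(), collapse = "/"), call. = FALSE)
  }
  rates <- c(capitalization = 0, unknown_term = 0, dependent_mismatch = 0,
             annotated_inaccurate = 0)
  rates[names(defect_rates)] <- defect_rates
  if (any(rates < 0 | rates > 1)) {
    stop("defect rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_codes = n_codes,
    tissues = tissues,
    sample_types = sample_types,
    defect_rates = rates,
    n_morphology = as.integer(n_morphology %||% max(8L, round(n_codes / 7))),
    n_topography = as.integer(n_topography %||% max(5L, round(n_codes / 19))),
    version_edit_script = version_edit_script),
    class = "leap_fixture_spec")
}

# run f under a pinned, restorable RNG (Mersenne-Twister + Rejection)
.with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  f()
}

.n_victims <- function(rate, n) {
  if (rate <= 0) 0L else max(1L, as.integer(round(rate * n)))
}

#' Generate a synthetic fixture world
#'
#' Produces, deterministically from the spec: version 1 of a classification
#' tree; version 2 obtained by applying an edit script (explicit via
#' `version_edit_script`, or a generated release-style script); a data
#' dictionary covering the seven GDC diagnosis attributes plus a
#' morphology-to-primary-diagnosis dependency rule; a denormalized mapping
#' sheet with one row per (code, sample type); reviewer annotations; and a
#' complete ground truth (every seeded defect expanded to the mapping rows
#' it reaches, the realized version edits, and the mapping-to-vocabulary
#' link topology).
#'
#' An explicit `version_edit_script` is a list of
#' `list(op = "add", code =, name =, main_type =, tissue =, parent =)`,
#' `list(op = "remove", code =)`, `list(op = "rename", code =, new_name =)`,
#' `list(op = "reparent", code =, new_parent =)`, or
#' `list(op = "refield", code =, field =, new_value =)`.
#'
#' @param spec A `leap_fixture_spec`.
#' @return An object of class `leap_world`: list with `spec`,
#'   `classification`, `classification_v2`, `dictionary`, `sheet`,
#'   `annotations`, `ground_truth`.
#' @export
leap_generate_world <- function(spec = leap_fixture_spec()) {
  stopifnot(inherits(spec, "leap_fixture_spec"))
  .with_seed(spec$seed, function() .build_world(spec))
}

.build_world <- function(spec) {
  n <- spec$n_codes
  tissues <- spec$tissues
  nt <- length(tissues)

  # ---- classification v1 ------------------------------------------------
  codes <- sprintf("OT%04d", seq_len(n))
  tissue_of <- character(n)
  tissue_of[seq_len(min(n, nt))] <- tissues[seq_len(min(n, nt))]  # roots
  if (n > nt) {
    tissue_of[(nt + 1L):n] <- sample(tissues, n - nt, replace = TRUE)
  }
  parent_of <- character(n)
  for (i in seq_len(n)) {
    if (i <= nt) next  # tissue roots
    earlier <- which(tissue_of[seq_len(i - 1L)] == tissue_of[[i]])
    parent_of[[i]] <- codes[if (length(earlier) == 1L) earlier else
      sample(earlier, 1L)]
  }
  v1 <- leap_classification("oncotree", "synthetic_v1", data.frame(
    code = codes,
    name = sprintf("%s neoplasm %d", tissue_of, seq_len(n)),
    main_type = sprintf("%s cancer", tissue_of),
    tissue = tissue_of,
    parent_code = parent_of,
    stringsAsFactors = FALSE))

  # ---- GDC vocabularies --------------------------------------------------
  nm <- spec$n_morphology
  np <- spec$n_topography
  morph <- data.frame(
    code = sprintf("%d/3", 8000L + sample(seq_len(1999L), nm)),
    primary_diagnosis = sprintf("Malignant neoplasm %s",
                                sprintf("M%03d", seq_len(nm))),
    tumor_grade = c("Not Reported", "Grade I", "Grade II",
                    "Grade III")[1L + (seq_len(nm) %% 4L)],
    disease_type = sprintf("Neoplasm Group %s",
                           LETTERS[1L + (seq_len(nm) %% 8L)]),
    stringsAsFactors = FALSE)
  topo <- data.frame(
    code = sprintf("C%02d.%d", sample(seq_len(80L), np),
                   (seq_len(np) %% 10L)),
    primary_site = sprintf("Primary Site %s", sprintf("S%02d", seq_len(np))),
    site_of_resection_or_biopsy = sprintf("Resection Site %s",
                                          sprintf("R%02d", seq_len(np))),
    stringsAsFactors = FALSE)

  dictionary <- leap_dictionary(
    attributes = list(
      primary_diagnosis = morph$primary_diagnosis,
      tissue_or_organ_of_origin = topo$code,
      tumor_grade = c("Not Reported", "Grade I", "Grade II", "Grade III"),
      morphology = morph$code,
      site_of_resection_or_biopsy = topo$site_of_resection_or_biopsy,
      primary_site = topo$primary_site,
      disease_type = sprintf("Neoplasm Group %s", LETTERS[1:8])),
    dependencies = list(list(
      key = "morphology", dependent = "primary_diagnosis",
      pairs = lapply(seq_len(nm), function(i) {
        c(morph$code[[i]], morph$primary_diagnosis[[i]])
      }))))

  morph_of <- sample(seq_len(nm), n, replace = TRUE)
  topo_of <- sample(seq_len(np), n, replace = TRUE)

  # ---- seeded defects ----------------------------------------------------
  rates <- spec$defect_rates
  n_cap <- .n_victims(rates[["capitalization"]], nm + np)
  n_unk <- .n_victims(rates[["unknown_term"]], nm + np)
  n_dep <- .n_victims(rates[["dependent_mismatch"]], nm)
  if (n_dep > 0L && nm < 2L) {
    stop("infeasible spec: dependent mismatches need >= 2 morphology entities",
         call. = FALSE)
  }
  if (n_cap + n_unk + n_dep > nm + np || n_dep > nm) {
    stop("infeasible spec: more seeded defects than vocabulary entities",
         call. = FALSE)
  }
  # value-defect-eligible attributes per vocabulary entity (link-key columns
  # morphology / tissue_or_organ_of_origin are never corrupted)
  morph_attrs <- c("primary_diagnosis", "tumor_grade", "disease_type")
  topo_attrs <- c("primary_site", "site_of_resection_or_biopsy")
  dep_victims <- sort(sample(seq_len(nm), n_dep))
  pool <- setdiff(seq_len(nm + np), dep_victims)  # 1..nm morph, nm+1.. topo
  value_victims <- sample(pool, n_cap + n_unk)
  cap_victims <- sort(value_victims[seq_len(n_cap)])
  unk_victims <- sort(setdiff(value_victims, cap_victims))

  corrupted <- list()  # (entity index, attribute, category)
  corrupt_value <- function(idx, how) {
    if (idx <= nm) {
      a <- sample(morph_attrs, 1L)
      val <- morph[[a]][[idx]]
      morph[[a]][[idx]] <<- how(val)
    } else {
      a <- sample(topo_attrs, 1L)
      val <- topo[[a]][[idx - nm]]
      topo[[a]][[idx - nm]] <<- how(val)
    }
    a
  }
  for (idx in cap_victims) {
    a <- corrupt_value(idx, tolower)
    corrupted[[length(corrupted) + 1L]] <-
      list(idx = idx, attribute = a, category = "CAPITALIZATION_MISMATCH")
  }
  for (idx in unk_victims) {
    a <- corrupt_value(idx, function(v) paste0(v, " (unlisted)"))
    corrupted[[length(corrupted) + 1L]] <-
      list(idx = idx, attribute = a, category = "UNKNOWN_TERM")
  }
  for (idx in dep_victims) {
    other <- if (idx == nm) 1L else idx + 1L
    morph$primary_diagnosis[[idx]] <-
      sprintf("Malignant neoplasm %s", sprintf("M%03d", other))
    corrupted[[length(corrupted) + 1L]] <-
      list(idx = idx, attribute = "primary_diagnosis",
           category = "DEPENDENT_FIELD_MISMATCH")
  }

  # ---- mapping sheet -----------------------------------------------------
  sts <- spec$sample_types
  ci <- rep(seq_len(n), each = length(sts))
  st <- rep(sts, times = n)
  sheet <- data.frame(
    label = paste0(codes[ci], "|", st),
    oncotree_code = codes[ci],
    sample_type = st,
    tissue = tissue_of[ci],
    main_type = v1$records$main_type[ci],
    name = v1$records$name[ci],
    morphology = morph$code[morph_of[ci]],
    primary_diagnosis = morph$primary_diagnosis[morph_of[ci]],
    tumor_grade = morph$tumor_grade[morph_of[ci]],
    disease_type = morph$disease_type[morph_of[ci]],
    tissue_or_organ_of_origin = topo$code[topo_of[ci]],
    primary_site = topo$primary_site[topo_of[ci]],
    site_of_resection_or_biopsy = topo$site_of_resection_or_biopsy[topo_of[ci]],
    stringsAsFactors = FALSE)

  # ---- annotations -------------------------------------------------------
  n_ann <- .n_victims(rates[["annotated_inaccurate"]], nrow(sheet))
  if (n_ann > nrow(sheet)) {
    stop("infeasible spec: more annotations than mapping rows", call. = FALSE)
  }
  ann_rows <- sort(sample(seq_len(nrow(sheet)), n_ann))
  annotations <- data.frame(
    label = sheet$label[ann_rows],
    note = rep(
      "reviewer: tissue_or_organ_of_origin/morphology link judged inaccurate",
      length(ann_rows)),
    stringsAsFactors = FALSE)

  # ---- ground truth: defects expanded to mapping rows --------------------
  defect_rows <- list()
  for (d in corrupted) {
    hit_codes <- if (d$idx <= nm) which(morph_of == d$idx) else
      which(topo_of == d$idx - nm)
    for (k in hit_codes) {
      for (s in sts) {
        defect_rows[[length(defect_rows) + 1L]] <- data.frame(
          entity_label = paste0(codes[[k]], "|", s),
          attribute = d$attribute, category = d$category,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_ann > 0L) {
    defect_rows[[length(defect_rows) + 1L]] <- data.frame(
      entity_label = annotations$label,
      attribute = leap_annotation_attribute(),
      category = "ANNOTATED_INACCURATE", stringsAsFactors = FALSE)
  }
  seeded <- if (length(defect_rows) > 0L) {
    out <- do.call(rbind, defect_rows)
    out <- out[order(out$entity_label, out$attribute, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(entity_label = character(0), attribute = character(0),
               category = character(0), stringsAsFactors = FALSE)
  }

  # ---- version 2 ---------------------------------------------------------
  script <- spec$version_edit_script %||% .release_edit_script(v1, tissues)
  v2_build <- .apply_edit_script(v1, script)

  link_topology <- data.frame(
    label = sheet$label,
    oncotree_code = sheet$oncotree_code,
    morphology = sheet$morphology,
    topography = sheet$tissue_or_organ_of_origin,
    stringsAsFactors = FALSE)

  structure(list(
    spec = spec,
    classification = v1,
    classification_v2 = v2_build$classification,
    dictionary = dictionary,
    sheet = sheet,
    annotations = annotations,
    ground_truth = list(
      seeded_defects = seeded,
      edits = v2_build$realized,
      link_topology = link_topology)),
    class = "leap_world")
}

# release-style default edit script: additions concentrated in the first
# two (myeloid/lymphoid) groups, echoing an OncoTree hematologic expansion
.release_edit_script <- function(v1, tissues) {
  rec <- v1$records
  n_add_target <- c(75L, 30L)
  extra_add <- 41L
  script <- list()
  add_i <- 0L
  add_to <- function(tissue, how_many) {
    parent <- rec$code[match(tissue, rec$tissue)]
    if (is.na(parent)) parent <- rec$code[[1L]]
    for (k in seq_len(how_many)) {
      add_i <<- add_i + 1L
      script[[length(script) + 1L]] <<- list(
        op = "add", code = sprintf("NEW%04d", add_i),
        name = sprintf("%s expansion neoplasm %d", tissue, add_i),
        main_type = sprintf("%s cancer", tissue),
        tissue = tissue, parent = parent)
    }
  }
  add_to(tissues[[1L]], n_add_target[[1L]])
  if (length(tissues) > 1L) add_to(tissues[[2L]], n_add_target[[2L]])
  others <- if (length(tissues) > 2L) tissues[-(1:2)] else tissues
  for (k in seq_len(extra_add)) {
    add_to(others[[1L + ((k - 1L) %% length(others))]], 1L)
  }
  # in-place changes on non-root codes; removals must be leaves
  non_root <- rec$code[nzchar(rec$parent_code)]
  is_leaf <- !(rec$code %in% rec$parent_code)
  pool <- sample(non_root)
  take <- function(k) {
    k <- min(k, length(pool))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  for (code in take(12L)) {
    script[[length(script) + 1L]] <- list(
      op = "rename", code = code,
      new_name = paste(rec$name[match(code, rec$code)], "NOS"))
  }
  for (code in take(8L)) {
    root <- rec$code[match(rec$tissue[match(code, rec$code)], rec$tissue)]
    if (identical(root, rec$parent_code[match(code, rec$code)])) next
    script[[length(script) + 1L]] <- list(
      op = "reparent", code = code, new_parent = root)
  }
  for (code in take(6L)) {
    script[[length(script) + 1L]] <- list(
      op = "refield", code = code, field = "main_type",
      new_value = paste(rec$main_type[match(code, rec$code)], "(revised)"))
  }
  leaves_in_pool <- pool[pool %in% rec$code[is_leaf]]
  for (code in utils::head(leaves_in_pool, 4L)) {
    script[[length(script) + 1L]] <- list(op = "remove", code = code)
  }
  script
}

.apply_edit_script <- function(v1, script) {
  rec <- v1$records
  added <- character(0)
  removed <- character(0)
  renamed <- list()
  reparented <- list()
  refielded <- list()
  for (e in script) {
    switch(e$op,
      add = {
        rec <- rbind(rec, data.frame(
          code = e$code, name = e$name, main_type = e$main_type,
          tissue = e$tissue, parent_code = e$parent %||% "",
          stringsAsFactors = FALSE))
        added <- c(added, e$code)
      },
      remove = {
        if (e$code %in% rec$parent_code) {
          stop(sprintf("edit script removes non-leaf code '%s'", e$code),
               call. = FALSE)
        }
        rec <- rec[rec$code != e$code, , drop = FALSE]
        removed <- c(removed, e$code)
      },
      rename = {
        i <- match(e$code, rec$code)
        renamed[[length(renamed) + 1L]] <- data.frame(
          code = e$code, old_name = rec$name[[i]], new_name = e$new_name,
          stringsAsFactors = FALSE)
        rec$name[[i]] <- e$new_name
      },
      reparent = {
        i <- match(e$code, rec$code)
        reparented[[length(reparented) + 1L]] <- data.frame(
          code = e$code, old_parent = rec$parent_code[[i]],
          new_parent = e$new_parent, stringsAsFactors = FALSE)
        rec$parent_code[[i]] <- e$new_parent
      },
      refield = {
        i <- match(e$code, rec$code)
        refielded[[length(refielded) + 1L]] <- data.frame(
          code = e$code, field = e$field, old = rec[[e$field]][[i]],
          new = e$new_value, stringsAsFactors = FALSE)
        rec[[e$field]][[i]] <- e$new_value
      },
      stop(sprintf("unknown edit op '%s'", e$op), call. = FALSE))
  }
  bind_sorted <- function(lst, cols) {
    if (length(lst) == 0L) {
      out <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols),
        stringsAsFactors = FALSE)
      return(out)
    }
    out <- do.call(rbind, lst)
    ord <- if ("field" %in% cols) order(out$code, out$field, method = "radix")
           else order(out$code, method = "radix")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(
    classification = leap_classification(v1$system, "synthetic_v2", rec),
    realized = list(
      added = sort(added),
      removed = sort(removed),
      renamed = bind_sorted(renamed, c("code", "old_name", "new_name")),
      reparented = bind_sorted(reparented, c("code", "old_parent", "new_parent")),
      refielded = bind_sorted(refielded, c("code", "field", "old", "new"))))
}

#' @export
print.leap_world <- function(x, ...) {
  cat(sprintf("<leap_world> seed %d: %d codes, %d mapping rows, %d seeded defect row(s)\n",
              x$spec$seed, nrow(x$classification$records), nrow(x$sheet),
              nrow(x$ground_truth$seeded_defects)))
  invisible(x)
}

#' Load a generated world into a store
#'
#' Loads classification version 1, the mapping sheet (links inheriting the
#' GDC descriptive fields), and the reviewer annotations.
#'
#' @param store A writable `leap_store`.
#' @param world A `leap_world`.
#' @return A list of the two import summaries plus `annotations_applied`.
#' @export
leap_load_world <- function(store, world) {
  stopifnot(inherits(world, "leap_world"))
  cls <- leap_load_classification(store, world$classification)
  map <- leap_load_mapping_sheet(store, world$sheet)
  for (i in seq_len(nrow(world$annotations))) {
    leap_annotate_inaccurate(store, world$annotations$label[[i]],
                             world$annotations$note[[i]])
  }
  list(classification = cls, mapping = map,
       annotations_applied = nrow(world$annotations))
}

#' Write a world's artifacts to a directory
#'
#' Emits `classification_v1.csv`, `classification_v2.csv`,
#' `dictionary.json`, `mapping_sheet.csv`, `annotations.csv` and
#' `ground_truth.json`. Output is byte-identical across runs for the same
#' spec.
#'
#' @param world A `leap_world`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
leap_write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  leap_write_classification(world$classification,
                            file.path(dir, "classification_v1.csv"))
  leap_write_classification(world$classification_v2,
                            file.path(dir, "classification_v2.csv"))
  leap_write_dictionary(world$dictionary, file.path(dir, "dictionary.json"))
  leap_write_table(world$sheet, file.path(dir, "mapping_sheet.csv"))
  leap_write_table(world$annotations, file.path(dir, "annotations.csv"))
  jsonlite::write_json(world$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
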