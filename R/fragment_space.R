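# Fragment/template library and combinatorial catalyst assembly.
#
# A catalyst template is a "flexible" SMILES scaffold carrying named
# placeholder tokens "{R1a}", "{R2b}", ... Each token names a slot bound to a
# substituent category (R1-R4). Assembly is literal string substitution of a
# fragment's SMILES into the token, followed by canonicalization. Fragments
# are written as branch strings attaching through their first atom, so a slot
# is normally placed in a parenthesized branch context, e.g. "c1ccc({R1a})cc1".

.FRAGMENT_CATEGORIES <- c("R1", "R2", "R3", "R4")

.placeholders <- function(scaffold) {
  m <- gregexpr("\\{([A-Za-z0-9_]+)\\}", scaffold)[[1]]
  if (m[1] == -1) return(character(0))
  gsub("[{}]", "", regmatches(scaffold, gregexpr("\\{([A-Za-z0-9_]+)\\}", scaffold))[[1]])
}

#' Create a catalyst template
#'
#' @param id unique template identifier.
#' @param family catalyst family label (e.g. "urea", "thiourea", "squaramide",
#'   "CPA-BINOL"); free text.
#' @param scaffold SMILES string containing each slot once as a `{slot}` token.
#' @param slots named character vector mapping slot name to fragment category
#'   (one of R1-R4).
#' @param symmetric_groups list of character vectors; the slots inside each
#'   group are constrained to carry identical fragments (e.g. the 6/6'
#'   positions of a BINOL/SPINOL phosphoric acid).
#' @return an object of class `catalyst_template`.
#' @export
catalyst_template <- function(id, family, scaffold, slots, symmetric_groups = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  slots <- unlist(slots)
  if (is.null(names(slots)) || any(!nzchar(names(slots)))) {
    stop("template '", id, "': slots must be a named vector (slot -> category)")
  }
  bad <- setdiff(unname(slots), .FRAGMENT_CATEGORIES)
  if (length(bad)) {
    stop("template '", id, "': unknown fragment category: ", paste(bad, collapse = ", "))
  }
  toks <- .placeholders(scaffold)
  if (anyDuplicated(toks)) {
    stop("template '", id, "': placeholder appears more than once: ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "))
  }
  missing_tok <- setdiff(names(slots), toks)
  if (length(missing_tok)) {
    stop("template '", id, "': scaffold lacks declared placeholder(s): ",
         paste(missing_tok, collapse = ", "))
  }
  extra_tok <- setdiff(toks, names(slots))
  if (length(extra_tok)) {
    stop("template '", id, "': scaffold placeholder(s) not declared as slots: ",
         paste(extra_tok, collapse = ", "))
  }
  symmetric_groups <- lapply(symmetric_groups, as.character)
  for (g in symmetric_groups) {
    if (length(g) < 2L) stop("template '", id, "': symmetric group needs >= 2 slots")
    unknown <- setdiff(g, names(slots))
    if (length(unknown)) {
      stop("template '", id, "': symmetric group references unknown slot(s): ",
           paste(unknown, collapse = ", "))
    }
    if (length(unique(slots[g])) != 1L) {
      stop("template '", id, "': symmetric group mixes categories: ",
           paste(g, collapse = ", "))
    }
  }
  structure(
    list(id = id, family = family, scaffold = scaffold,
         slots = slots, symmetric_groups = symmetric_groups),
    class = "catalyst_template"
  )
}

#' Create a substituent fragment
#'
#' @param id unique fragment identifier.
#' @param smiles SMILES of the substituent written as a branch string; the
#'   first atom is the attachment point.
#' @param category fragment category, one of R1-R4.
#' @return an object of class `catalyst_fragment`.
#' @export
catalyst_fragment <- function(id, smiles, category) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!category %in% .FRAGMENT_CATEGORIES) {
    stop("fragment '", id, "': unknown category '", category, "'")
  }
  if (grepl("[{}]", smiles)) {
    stop("fragment '", id, "': SMILES must not contain placeholder tokens")
  }
  # Attachment check: the fragment must be valid when spliced into a probe
  # branch context (single attachment point through its first atom).
  if (!is_valid_smiles(paste0("C(", smiles, ")"))) {
    stop("fragment '", id, "': SMILES '", smiles,
         "' is not a valid single-attachment substituent")
  }
  structure(list(id = id, smiles = smiles, category = category),
            class = "catalyst_fragment")
}

#' Build a catalyst library from templates and fragments
#'
#' Validates all invariants eagerly: unique ids, parseable fragment SMILES,
#' declared categories, and that each template assembles to a valid molecule
#' with a representative fragment in every slot.
#'
#' @param templates list of [catalyst_template()] objects.
#' @param fragments list of [catalyst_fragment()] objects.
#' @return an object of class `catalyst_library`.
#' @export
catalyst_library <- function(templates, fragments) {
  stopifnot(length(templates) > 0L, length(fragments) > 0L)
  tids <- vapply(templates, `[[`, character(1), "id")
  fids <- vapply(fragments, `[[`, character(1), "id")
  if (anyDuplicated(tids)) stop("duplicate template id: ", tids[duplicated(tids)][1])
  if (anyDuplicated(fids)) stop("duplicate fragment id: ", fids[duplicated(fids)][1])
  names(templates) <- tids
  names(fragments) <- fids
  lib <- structure(
    list(templates = templates, fragments = fragments,
         by_category = split(fids, vapply(fragments, `[[`, character(1), "category"))),
    class = "catalyst_library"
  )
  # smoke-assemble every template with the first compatible fragment per slot
  for (tpl in templates) {
    asg <- vapply(names(tpl$slots), function(slot) {
      cat <- tpl$slots[[slot]]
      pool <- lib$by_category[[cat]]
      if (is.null(pool) || !length(pool)) {
        stop("template '", tpl$id, "' slot '", slot,
             "' references empty category ", cat)
      }
      pool[1]
    }, character(1))
    for (g in tpl$symmetric_groups) asg[g] <- asg[g[1]]
    assemble(tpl, as.list(asg), lib)
  }
  lib
}

#' Load a catalyst library from CSV files
#'
#' `templates_file` needs columns `id, family, scaffold, slots,
#' symmetric_groups`; `slots` is semicolon-separated `slot:category` pairs and
#' `symmetric_groups` is semicolon-separated groups of comma-separated slot
#' names (may be empty). `fragments_file` needs columns `id, smiles, category`.
#'
#' @param templates_file,fragments_file CSV paths.
#' @return an object of class `catalyst_library`.
#' @export
load_library <- function(templates_file, fragments_file) {
  ft <- utils::read.csv(templates_file, stringsAsFactors = FALSE)
  ff <- utils::read.csv(fragments_file, stringsAsFactors = FALSE)
  need_t <- c("id", "family", "scaffold", "slots", "symmetric_groups")
  need_f <- c("id", "smiles", "category")
  if (!all(need_t %in% names(ft))) {
    stop("templates file must have columns: ", paste(need_t, collapse = ", "))
  }
  if (!all(need_f %in% names(ff))) {
    stop("fragments file must have columns: ", paste(need_f, collapse = ", "))
  }
  fragments <- lapply(seq_len(nrow(ff)), function(i) {
    tryCatch(catalyst_fragment(ff$id[i], ff$smiles[i], ff$category[i]),
             error = function(e) stop("fragments row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  templates <- lapply(seq_len(nrow(ft)), function(i) {
    slot_spec <- strsplit(trimws(strsplit(ft$slots[i], ";")[[1]]), ":")
    slots <- vapply(slot_spec, function(p) {
      if (length(p) != 2L) stop("templates row ", i, ": malformed slot spec", call. = FALSE)
      trimws(p[2])
    }, character(1))
    names(slots) <- vapply(slot_spec, function(p) trimws(p[1]), character(1))
    sg <- ft$symmetric_groups[i]
    groups <- list()
    if (!is.na(sg) && nzchar(trimws(sg))) {
      groups <- lapply(strsplit(sg, ";")[[1]], function(g) trimws(strsplit(g, ",")[[1]]))
    }
    tryCatch(catalyst_template(ft$id[i], ft$family[i], ft$scaffold[i], slots, groups),
             error = function(e) stop("templates row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  catalyst_library(templates, fragments)
}

#' Write a catalyst library to CSV files
#'
#' @param library a `catalyst_library`.
#' @param templates_file,fragments_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_library <- function(library, templates_file, fragments_file) {
  ft <- do.call(rbind, lapply(library$templates, function(t) {
    data.frame(
      id = t$id, family = t$family, scaffold = t$scaffold,
      slots = paste(paste0(names(t$slots), ":", t$slots), collapse = ";"),
      symmetric_groups = paste(vapply(t$symmetric_groups, paste, character(1),
                                      collapse = ","), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  ff <- do.call(rbind, lapply(library$fragments, function(f) {
    data.frame(id = f$id, smiles = f$smiles, category = f$category,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ft, templates_file, row.names = FALSE)
  utils::write.csv(ff, fragments_file, row.names = FALSE)
  invisible(c(templates_file, fragments_file))
}

#' Assemble a catalyst candidate from a template and a slot assignment
#'
#' Substitutes each slot's fragment SMILES into the scaffold token and
#' canonicalizes the result. Deterministic: identical inputs give an identical
#' canonical SMILES.
#'
#' @param template a `catalyst_template`.
#' @param assignment named list/vector mapping every slot to a fragment id.
#' @param library the `catalyst_library` owning the fragments.
#' @return an object of class `catalyst_candidate` with fields `template_id`,
#'   `assignment`, `smiles`.
#' @export
assemble <- function(template, assignment, library) {
  assignment <- unlist(assignment)
  missing_slots <- setdiff(names(template$slots), names(assignment))
  if (length(missing_slots)) {
    stop("assembly error: assignment misses slot(s): ",
         paste(missing_slots, collapse = ", "))
  }
  for (g in template$symmetric_groups) {
    if (length(unique(assignment[g])) != 1L) {
      stop("assembly error: symmetric slots {", paste(g, collapse = ", "),
           "} must carry identical fragments")
    }
  }
  smi <- template$scaffold
  for (slot in names(template$slots)) {
    fid <- assignment[[slot]]
    frag <- library$fragments[[fid]]
    if (is.null(frag)) stop("assembly error: unknown fragment id '", fid, "'")
    if (frag$category != template$slots[[slot]]) {
      stop("assembly error: slot '", slot, "' needs category ",
           template$slots[[slot]], " but fragment '", fid, "' is ", frag$category)
    }
    smi <- sub(paste0("{", slot, "}"), frag$smiles, smi, fixed = TRUE)
  }
  can <- canonical_smiles(smi)
  if (is.na(can)) {
    stop("assembly error: template '", template$id,
         "' with assignment yields unparseable SMILES: ", smi)
  }
  structure(
    list(template_id = template$id,
         assignment = assignment[names(template$slots)],
         smiles = can),
    class = "catalyst_candidate"
  )
}

# Independent slot groups of a template: symmetric groups collapse to one
# degree of freedom each.
.slot_groups <- function(template) {
  grouped <- unlist(template$symmetric_groups)
  free <- setdiff(names(template$slots), grouped)
  c(lapply(free, function(s) s), template$symmetric_groups)
}

#' Size of the combinatorial catalyst space
#'
#' Counts assignments: the sum over templates of the product over independent
#' slot groups of the category size (a symmetric group contributes one factor).
#'
#' @param library a `catalyst_library`.
#' @return a numeric count (may exceed integer range).
#' @export
enumerate_count <- function(library) {
  sum(vapply(library$templates, function(tpl) {
    prod(vapply(.slot_groups(tpl), function(g) {
      cat <- tpl$slots[[g[1]]]
      n <- length(library$by_category[[cat]])
      if (n == 0L) stop("template '", tpl$id, "': empty category ", cat)
      as.numeric(n)
    }, numeric(1)))
  }, numeric(1)))
}

#' Enumerate every candidate in a (small) catalyst space
#'
#' @param library a `catalyst_library`.
#' @param max_size guard against accidental enumeration of huge spaces.
#' @return list of `catalyst_candidate` objects, ordered template-major with
#'   the last slot group varying fastest.
#' @export
enumerate_all <- function(library, max_size = 1e5) {
  n <- enumerate_count(library)
  if (n > max_size) {
    stop("candidate space has ", format(n, big.mark = ","),
         " assignments; raise max_size or use a smaller library")
  }
  out <- vector("list", n)
  k <- 0L
  for (tpl in library$templates) {
    groups <- .slot_groups(tpl)
    pools <- lapply(groups, function(g) library$by_category[[tpl$slots[[g[1]]]]])
    grid <- expand.grid(rev(pools), stringsAsFactors = FALSE)[, rev(seq_along(pools)), drop = FALSE]
    for (i in seq_len(nrow(grid))) {
      asg <- character(length(tpl$slots))
      names(asg) <- names(tpl$slots)
      for (j in seq_along(groups)) asg[groups[[j]]] <- grid[i, j]
      k <- k + 1L
      out[[k]] <- assemble(tpl, as.list(asg), library)
    }
  }
  out
}

#' Draw a random catalyst candidate
#'
#' Samples uniformly over the assignment space: templates are drawn with
#' probability proportional to their assignment count, then each independent
#' slot group uniformly from its category. Uses the R RNG, so `set.seed()`
#' makes draws reproducible.
#'
#' @param library a `catalyst_library`.
#' @param n number of candidates to draw.
#' @return a `catalyst_candidate` if `n == 1`, else a list of them.
#' @export
sample_candidate <- function(library, n = 1L) {
  sizes <- vapply(library$templates, function(tpl) {
    prod(vapply(.slot_groups(tpl), function(g)
      length(library$by_category[[tpl$slots[[g[1]]]]]), numeric(1)))
  }, numeric(1))
  if (any(sizes == 0)) stop("library has a slot with an empty category")
  draws <- lapply(seq_len(n), function(i) {
    tpl <- library$templates[[sample.int(length(sizes), 1L, prob = sizes)]]
    asg <- character(length(tpl$slots))
    names(asg) <- names(tpl$slots)
    for (g in .slot_groups(tpl)) {
      pool <- library$by_category[[tpl$slots[[g[1]]]]]
      asg[g] <- pool[sample.int(length(pool), 1L)]
    }
    assemble(tpl, as.list(asg), library)
  })
  if (n == 1L) draws[[1]] else draws
}

#' @export
print.catalyst_library <- function(x, ...) {
  cat("catalyst_library:", length(x$templates), "templates,",
      length(x$fragments), "fragments\n")
  cat("  categories:",
      paste(names(x$by_category), vapply(x$by_category, length, integer(1)),
            sep = "=", collapse = ", "), "\n")
  cat("  assignment space:", format(enumerate_count(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.catalyst_candidate <- function(x, ...) {
  cat("catalyst_candidate [", x$template_id, "] ", x$smiles, "\n", sep = "")
  cat("  ", paste(names(x$assignment), x$assignment, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
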