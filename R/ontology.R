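#' Interaction ontologies
#'
#' An interaction ontology is a rooted tree of interaction types (terms).
#' Membership of a gene pair in a term implies membership in every ancestor
#' term ("true-path" semantics), and each term is either directed (gene
#' pairs of that type are ordered, e.g. kinase -> substrate) or undirected
#' (e.g. physical association). The tree doubles as the skeleton of the
#' Bayesian network used to reconcile per-term classifier scores.
#'
#' @param terms a data.frame with columns `id` (character, unique),
#'   `parent` (character, `NA` for the single root), `directed` (logical)
#'   and `name` (character).
#' @return An object of class `interaction_ontology`: a list with elements
#'   `terms` (the validated data.frame), `children` (named list, file-order
#'   child ids per term) and `root` (the root id).
#' @examples
#' o <- interaction_ontology(data.frame(
#'   id = c("root", "physical", "pathway"),
#'   parent = c(NA, "root", "root"),
#'   directed = FALSE,
#'   name = c("functional relationship", "physical interaction",
#'            "pathway interaction")))
#' ontology_terms(o)
#' @export
interaction_ontology <- function(terms) {
  stopifnot(is.data.frame(terms))
  need <- c("id", "parent", "directed", "name")
  if (!all(need %in% names(terms))) {
    stop("ontology terms need columns: ", paste(need, collapse = ", "))
  }
  terms$id <- as.character(terms$id)
  terms$parent <- as.character(terms$parent)
  terms$directed <- as.logical(terms$directed)
  terms$name <- as.character(terms$name)
  rownames(terms) <- NULL

  dup <- terms$id[duplicated(terms$id)]
  if (length(dup)) {
    line <- which(terms$id %in% dup)[2]
    stop(sprintf("duplicate term id '%s' (entry %d)", dup[1], line))
  }
  is_root <- is.na(terms$parent)
  if (sum(is_root) == 0L) stop("no root term (every term has a parent)")
  if (sum(is_root) > 1L) {
    stop(sprintf("multiple roots: %s",
                 paste(terms$id[is_root], collapse = ", ")))
  }
  dangling <- !is_root & !(terms$parent %in% terms$id)
  if (any(dangling)) {
    i <- which(dangling)[1]
    stop(sprintf("dangling parent '%s' of term '%s' (entry %d)",
                 terms$parent[i], terms$id[i], i))
  }
  root <- terms$id[is_root]

  # Cycle check: walking up from any term must reach the root in <= n steps.
  parent_of <- stats::setNames(terms$parent, terms$id)
  n <- nrow(terms)
  for (id in terms$id) {
    cur <- id
    steps <- 0L
    while (!is.na(parent_of[[cur]])) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      if (steps > n) {
        stop(sprintf("cycle in parent chain starting at term '%s'", id))
      }
    }
  }

  children <- lapply(stats::setNames(terms$id, terms$id), function(id) {
    terms$id[!is.na(terms$parent) & terms$parent == id]
  })
  structure(list(terms = terms, children = children, root = root),
            class = "interaction_ontology")
}

#' @export
print.interaction_ontology <- function(x, ...) {
  cat(sprintf("interaction ontology: %d terms, root '%s', %d directed\n",
              nrow(x$terms), x$root, sum(x$terms$directed)))
  invisible(x)
}

#' @rdname interaction_ontology
#' @param o an `interaction_ontology`.
#' @export
ontology_terms <- function(o) o$terms$id

#' @rdname interaction_ontology
#' @param id a term id.
#' @export
is_directed_term <- function(o, id) {
  check_term(o, id)
  o$terms$directed[match(id, o$terms$id)]
}

#' @rdname interaction_ontology
#' @export
leaf_terms <- function(o) names(o$children)[lengths(o$children) == 0L]

check_term <- function(o, id) {
  missing <- setdiff(id, o$terms$id)
  if (length(missing)) {
    stop(sprintf("unknown term(s): %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read / write the tab-delimited ontology format
#'
#' One term per line: `term_id <TAB> parent_id|"-" <TAB> directed(0/1)
#' <TAB> name`. `"-"` marks the root. Parse errors name the offending line.
#'
#' @param path file path.
#' @return `load_ontology()` returns an `interaction_ontology`;
#'   `write_ontology()` returns `path` invisibly. The writer mirrors the
#'   reader bit-exactly (round trips preserve structure and term order).
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty ontology file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected >= 3 tab-separated fields", bad[1]))
  }
  terms <- data.frame(
    id = vapply(fields, `[`, "", 1L),
    parent = vapply(fields, `[`, "", 2L),
    directed = vapply(fields, `[`, "", 3L),
    name = vapply(fields, function(f) if (length(f) >= 4L) f[4L] else "", ""),
    stringsAsFactors = FALSE
  )
  terms$parent[terms$parent == "-"] <- NA_character_
  if (!all(terms$directed %in% c("0", "1"))) {
    i <- which(!(terms$directed %in% c("0", "1")))[1]
    stop(sprintf("line %d: directed flag must be 0 or 1, got '%s'",
                 i, terms$directed[i]))
  }
  terms$directed <- terms$directed == "1"
  interaction_ontology(terms)
}

#' @rdname load_ontology
#' @param o an `interaction_ontology`.
#' @export
write_ontology <- function(o, path) {
  t <- o$terms
  lines <- sprintf("%s\t%s\t%d\t%s", t$id,
                   ifelse(is.na(t$parent), "-", t$parent),
                   as.integer(t$directed), t$name)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a minimal OBO-subset ontology
#'
#' Understands `[Term]` stanzas with `id:`, `name:`, `is_a:` tags and an
#' optional `property_value: directed true` (or `directed: true`) tag.
#' Term order follows file order.
#'
#' @param path file path to an OBO-subset file.
#' @return an `interaction_ontology`.
#' @export
load_ontology_obo <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = "", parent = NA_character_,
                  directed = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur$name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        v <- trimws(sub("^is_a:", "", ln))
        cur$parent <- trimws(strsplit(v, "!", fixed = TRUE)[[1]][1])
      } else if (grepl("^(property_value:\\s*)?directed[: ]", ln)) {
        cur$directed <- grepl("true", ln, fixed = TRUE)
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)
  interaction_ontology(data.frame(
    id = vapply(terms, `[[`, "", "id"),
    parent = vapply(terms, `[[`, "", "parent"),
    directed = vapply(terms, `[[`, TRUE, "directed"),
    name = vapply(terms, `[[`, "", "name"),
    stringsAsFactors = FALSE
  ))
}

#' Ancestors of a term
#'
#' @param o an `interaction_ontology`.
#' @param id a term id.
#' @return Character vector of term ids on the path from `id`'s parent up
#'   to the root, exclusive of `id` (empty for the root). Its length equals
#'   the term's depth.
#' @export
ancestors <- function(o, id) {
  check_term(o, id)
  parent_of <- stats::setNames(o$terms$parent, o$terms$id)
  out <- character()
  cur <- parent_of[[id]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

#' @rdname ancestors
#' @return `term_depths()` returns a named integer vector of depths
#'   (root = 0).
#' @export
term_depths <- function(o) {
  vapply(stats::setNames(o$terms$id, o$terms$id),
         function(id) length(ancestors(o, id)), 0L)
}

# Children-before-parents traversal order (reverse BFS from the root).
postorder_terms <- function(o) {
  order <- o$root
  frontier <- o$children[[o$root]]
  while (length(frontier)) {
    order <- c(order, frontier)
    frontier <- unlist(o$children[frontier], use.names = FALSE)
  }
  rev(order)
}

#' Restrict an ontology to a subset of terms
#'
#' The subset must be closed under taking parents (as produced by
#' [filter_terms()]), so the induced structure is again a rooted tree.
#'
#' @param o an `interaction_ontology`.
#' @param ids term ids to keep.
#' @return an `interaction_ontology` over `ids`, preserving term order.
#' @export
subset_ontology <- function(o, ids) {
  check_term(o, ids)
  keep <- o$terms[o$terms$id %in% ids, , drop = FALSE]
  orphan <- !is.na(keep$parent) & !(keep$parent %in% keep$id)
  if (any(orphan)) {
    stop("subset is not parent-closed; missing parents of: ",
         paste(keep$id[orphan], collapse = ", "))
  }
  interaction_ontology(keep)
}

#' Select modeled terms by annotation support
#'
#' Keeps terms whose positive-annotation count strictly exceeds
#' `min_annotations`. After true-path propagation parent counts dominate
#' child counts, so the result is closed under taking parents; if
#' unpropagated counts break that closure the missing ancestors are added
#' with a warning.
#'
#' @param o an `interaction_ontology`.
#' @param counts named numeric vector of positive-annotation counts, one
#'   entry per term of `o`.
#' @param min_annotations threshold (default 70); a term is kept when
#'   `counts > min_annotations`.
#' @return character vector of retained term ids (in ontology order).
#' @export
filter_terms <- function(o, counts, min_annotations = 70) {
  missing <- setdiff(o$terms$id, names(counts))
  if (length(missing)) {
    stop("counts missing for term(s): ", paste(missing, collapse = ", "))
  }
  keep <- o$terms$id[counts[o$terms$id] > min_annotations]
  closed <- unique(c(keep, unlist(lapply(keep, ancestors, o = o))))
  if (length(setdiff(closed, keep))) {
    warning("added ancestor term(s) below threshold to keep the set ",
            "parent-closed: ", paste(setdiff(closed, keep), collapse = ", "))
  }
  o$terms$id[o$terms$id %in% closed]
}
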