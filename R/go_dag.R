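# Gene Ontology DAG: construction, OBO parsing, propagation, depth and
# path-overlap semantic similarity.

#' Construct a GO DAG object
#'
#' Builds the directed acyclic graph of GO terms used throughout the package.
#' Edges point from a term to its direct parents (`is_a`, optionally
#' `part_of`). Each of the three GO namespaces (biological_process,
#' molecular_function, cellular_component) is kept separate: there is no
#' artificial super-root, and propagation, depth and similarity never cross a
#' namespace boundary.
#'
#' @param parents named list mapping each term id to a character vector of its
#'   direct parent ids (empty vector for roots). Names define the term set.
#' @param namespace named character vector mapping each term id to its
#'   namespace.
#' @param alt_ids named character vector mapping alternative (secondary) ids
#'   to primary term ids. May be empty.
#' @param names optional named character vector of human-readable term names.
#'
#' @return An object of class `go_dag` with elements `terms`, `parents`,
#'   `children`, `namespace`, `roots`, `alt_ids`, `ancestors` (the full
#'   ancestor closure of every term, including the term itself).
#'
#' @details The constructor validates the structural invariants: the parent
#'   graph must be acyclic, every parent must be a known term in the same
#'   namespace, and roots (parentless terms) anchor their namespace. The
#'   ancestor closure is precomputed once; all queries are lookups.
#'
#' @examples
#' dag <- go_dag(
#'   parents = list("GO:0000001" = character(),
#'                  "GO:0000002" = "GO:0000001",
#'                  "GO:0000003" = "GO:0000002"),
#'   namespace = c("GO:0000001" = "biological_process",
#'                 "GO:0000002" = "biological_process",
#'                 "GO:0000003" = "biological_process"))
#' propagate(dag, "GO:0000003")
#' @export
go_dag <- function(parents, namespace, alt_ids = character(), names = NULL) {
  terms <- base::names(parents)
  if (is.null(terms) || anyDuplicated(terms) > 0)
    stop("'parents' must be a uniquely named list of terms")
  parents <- lapply(parents, as.character)
  if (!all(terms %in% base::names(namespace)))
    stop("every term needs a namespace entry")
  namespace <- namespace[terms]

  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, terms)
  if (length(missing) > 0)
    stop("unknown parent term(s): ", paste(missing, collapse = ", "))
  for (t in terms) {
    ps <- parents[[t]]
    if (length(ps) > 0 && any(namespace[ps] != namespace[[t]]))
      stop("term ", t, " has a parent in a different namespace")
  }

  ancestors <- ancestor_closure(parents)  # also detects cycles

  roots <- terms[vapply(parents, length, 1L) == 0L]
  if (length(roots) == 0L) stop("DAG has no root term")

  children <- vector("list", length(terms))
  base::names(children) <- terms
  for (t in terms) children[[t]] <- character()
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)

  if (length(alt_ids) > 0) {
    alt_ids <- unlist(alt_ids)
    bad <- setdiff(unname(alt_ids), terms)
    if (length(bad) > 0)
      stop("alt_id target(s) not in DAG: ", paste(bad, collapse = ", "))
  }

  structure(
    list(terms = terms, parents = parents, children = children,
         namespace = namespace, roots = roots,
         alt_ids = alt_ids, names = names, ancestors = ancestors),
    class = "go_dag")
}

# Full ancestor closure (including self) for every term, by memoized DFS.
# Errors on cycles: a term revisited while on the active path.
ancestor_closure <- function(parents) {
  terms <- names(parents)
  closure <- vector("list", length(terms))
  names(closure) <- terms
  state <- new.env(parent = emptyenv())  # "active" / "done"

  visit <- function(t) {
    st <- state[[t]]
    if (identical(st, "done")) return(closure[[t]])
    if (identical(st, "active"))
      stop("cycle detected in ontology at term ", t)
    state[[t]] <- "active"
    anc <- t
    for (p in parents[[t]]) anc <- union(anc, visit(p))
    closure[[t]] <<- anc
    state[[t]] <- "done"
    anc
  }
  for (t in terms) visit(t)
  closure
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- table(x$namespace)
  cat("go_dag with", length(x$terms), "terms,",
      sum(lengths(x$parents)), "parent edges\n")
  cat("namespaces:", paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  cat("roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Load a GO DAG from an OBO flat file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2/1.4 file. Obsolete terms are
#' excluded, `alt_id` entries are recorded so that secondary ids resolve to
#' their primary term, and the edge set is restricted to the requested
#' relations (`is_a` always; `part_of` optionally, read from
#' `relationship: part_of` lines).
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @param relations relations to keep as parent edges. Default `"is_a"`;
#'   include `"part_of"` to also follow part-of relationships.
#'
#' @return a [go_dag] object.
#' @export
load_obo <- function(path, relations = "is_a") {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path) else unlist(strsplit(path, "\n", fixed = TRUE))

  default_ns <- "biological_process"
  dn <- grep("^default-namespace:", lines, value = TRUE)
  if (length(dn) > 0)
    default_ns <- trimws(sub("^default-namespace:", "", dn[[1]]))

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas found")

  parents <- list(); namespace <- character(); alt_ids <- character()
  term_names <- character()

  for (s in term_starts) {
    later <- stanza_starts[stanza_starts > s]
    end <- if (length(later) > 0) min(later) - 1L else length(lines)
    body <- lines[(s + 1L):end]
    body_lineno <- (s + 1L):end
    keep <- nzchar(trimws(body)) & !startsWith(trimws(body), "!")
    body <- body[keep]; body_lineno <- body_lineno[keep]
    if (length(body) == 0) next

    bad <- !grepl("^[A-Za-z_]+:", body)
    if (any(bad))
      stop("malformed OBO tag at line ", body_lineno[which(bad)[1]], ": ",
           body[which(bad)[1]])
    tags <- sub(":.*$", "", body)
    vals <- trimws(sub("^[A-Za-z_]+:", "", body))
    vals <- trimws(sub("!.*$", "", vals))  # strip trailing comments

    id <- vals[tags == "id"]
    if (length(id) != 1L)
      stop("stanza near line ", s, " must have exactly one id")
    if (any(tags == "is_obsolete" & vals == "true")) next

    ns <- vals[tags == "namespace"]
    namespace[[id]] <- if (length(ns) > 0) ns[[1]] else default_ns
    nm <- vals[tags == "name"]
    if (length(nm) > 0) term_names[[id]] <- nm[[1]]

    ps <- character()
    if ("is_a" %in% relations) ps <- c(ps, vals[tags == "is_a"])
    if ("part_of" %in% relations) {
      rel <- vals[tags == "relationship"]
      po <- grep("^part_of\\s", rel, value = TRUE)
      ps <- c(ps, trimws(sub("^part_of\\s+", "", po)))
    }
    parents[[id]] <- unique(ps)

    for (a in vals[tags == "alt_id"]) alt_ids[[a]] <- id
  }

  # drop edges to terms that were obsolete or absent
  known <- names(parents)
  dropped <- character()
  for (t in known) {
    unknown <- setdiff(parents[[t]], known)
    if (length(unknown) > 0) {
      dropped <- c(dropped, unknown)
      parents[[t]] <- setdiff(parents[[t]], unknown)
    }
  }
  if (length(dropped) > 0)
    warning("dropped edges to ", length(unique(dropped)),
            " obsolete/unknown parent term(s)")

  go_dag(parents, namespace, alt_ids = alt_ids, names = term_names)
}

#' Resolve term identifiers against a DAG
#'
#' Maps alternative (secondary) ids to their primary term. Unknown terms
#' either raise an error naming the offending id or are silently dropped.
#'
#' @param dag a [go_dag].
#' @param terms character vector of term ids.
#' @param on_missing `"error"` (default) or `"skip"` (drop with a warning).
#' @return character vector of primary term ids.
#' @export
resolve_terms <- function(dag, terms, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  terms <- as.character(terms)
  is_alt <- terms %in% names(dag$alt_ids)
  terms[is_alt] <- unname(dag$alt_ids[terms[is_alt]])
  unknown <- !(terms %in% dag$terms)
  if (any(unknown)) {
    if (on_missing == "error")
      stop("unknown GO term(s): ", paste(unique(terms[unknown]), collapse = ", "))
    warning("skipping unknown GO term(s): ",
            paste(unique(terms[unknown]), collapse = ", "))
    terms <- terms[!unknown]
  }
  terms
}

#' Propagate GO terms to the namespace root
#'
#' Expands a set of GO terms to include every ancestor on every path toward
#' the root of its namespace (the "true-path rule"). The result is a superset
#' of the input and the operation is idempotent.
#'
#' @param dag a [go_dag].
#' @param terms character vector of term ids (alt ids accepted).
#' @param on_missing behaviour for unknown terms, see [resolve_terms()].
#' @return character vector: the union of the input terms and all ancestors.
#' @export
propagate <- function(dag, terms, on_missing = c("error", "skip")) {
  terms <- resolve_terms(dag, terms, on_missing)
  if (length(terms) == 0) return(character())
  unique(unlist(dag$ancestors[terms], use.names = FALSE))
}

#' Depth of a GO term
#'
#' Number of nodes (both endpoints included) on a path from the term to its
#' namespace root, so the root itself has depth 1. In a DAG a term can reach
#' the root along several paths; the `convention` argument selects the
#' shortest (default) or longest path.
#'
#' @param dag a [go_dag].
#' @param terms character vector of term ids.
#' @param convention `"shortest"` or `"longest"` root path.
#' @return integer vector of depths.
#' @export
term_depth <- function(dag, terms, convention = c("shortest", "longest")) {
  convention <- match.arg(convention)
  terms <- resolve_terms(dag, terms)
  key <- paste0(".depth_", convention)
  depths <- attr(dag, key)
  if (is.null(depths)) {
    agg <- if (convention == "shortest") min else max
    depths <- integer(0)
    visit <- function(t) {
      if (!is.na(depths[t])) return(depths[t])
      ps <- dag$parents[[t]]
      d <- if (length(ps) == 0) 1L else 1L + agg(vapply(ps, visit, 1L))
      depths[t] <<- d
      d
    }
    depths <- stats::setNames(rep(NA_integer_, length(dag$terms)), dag$terms)
    for (t in dag$terms) visit(t)
  }
  unname(depths[terms])
}

#' Path-overlap semantic similarity of two GO terms
#'
#' For terms `g1`, `g2` with root-path node sets `r1`, `r2` (realized as the
#' full ancestor closure of each term, the term itself included), the
#' similarity is `|r1 n r2| / max(|r1|, |r2|)`: the number of shared nodes on
#' the paths to the root, relative to the larger path set. The score lies in
#' \[0, 1\], is symmetric, and equals 1 exactly when the closures coincide.
#' Terms from different namespaces share no path nodes; their similarity is
#' defined as 0 (with a warning).
#'
#' @param dag a [go_dag].
#' @param g1,g2 term ids.
#' @return numeric scalar in \[0, 1\].
#' @export
semantic_similarity <- function(dag, g1, g2) {
  g1 <- resolve_terms(dag, g1); g2 <- resolve_terms(dag, g2)
  if (dag$namespace[[g1]] != dag$namespace[[g2]]) {
    warning("terms ", g1, " and ", g2,
            " are in different namespaces; similarity is 0")
    return(0)
  }
  r1 <- dag$ancestors[[g1]]; r2 <- dag$ancestors[[g2]]
  length(intersect(r1, r2)) / max(length(r1), length(r2))
}

#' Write ancestor closures as a two-column TSV
#'
#' One row per (term, ancestor) pair, the term itself included in its own
#' closure.
#'
#' @param dag a [go_dag].
#' @param path output file path.
#' @return invisibly, the number of rows written.
#' @export
write_ancestors_tsv <- function(dag, path) {
  rows <- data.frame(
    term = rep(dag$terms, lengths(dag$ancestors)),
    ancestor = unlist(dag$ancestors, use.names = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(rows))
}

#' Write a GO DAG as an OBO flat file
#'
#' Emits one `[Term]` stanza per term with `id`, `namespace` and `is_a`
#' lines, suitable for round-tripping through [load_obo()].
#'
#' @param dag a [go_dag].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("default-namespace: ", dag$namespace[[1]]), ""), con)
  for (t in dag$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    if (!is.null(dag$names) && t %in% names(dag$names))
      writeLines(paste0("name: ", dag$names[[t]]), con)
    writeLines(paste0("namespace: ", dag$namespace[[t]]), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}
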