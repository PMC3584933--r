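# Domain co-occurrence networks (DCNs) and level-3 prediction by aggregated
# neighbor-counting.

#' Construct a per-species domain assignment table
#'
#' Records, for one species, which Pfam-style domain families occur in each
#' protein of its proteome. A protein may carry a domain family more than
#' once, and proteins without detected domains are allowed.
#'
#' @param species species identifier.
#' @param proteins named list mapping protein ids to character vectors of
#'   domain-family ids (order preserved; repeats allowed).
#' @return object of class `domain_assignments`.
#' @export
domain_assignments <- function(species, proteins) {
  if (length(proteins) > 0 && is.null(names(proteins)))
    stop("'proteins' must be named by protein id")
  structure(list(species = as.character(species),
                 proteins = lapply(proteins, as.character)),
            class = "domain_assignments")
}

#' Read domain assignment tables from TSV
#'
#' The on-disk format is a 3-column TSV: species, protein id,
#' comma-separated domain list (possibly empty). One file may carry several
#' species; one `domain_assignments` object is returned per species.
#'
#' @param path path to a file, or a character vector of lines.
#' @return named list of `domain_assignments`, one per species.
#' @export
read_assignments_tsv <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2))
    stop("line ", which(nf < 2)[1], ": expected >= 2 tab-separated columns")
  sp <- vapply(parts, `[[`, "", 1L)
  pr <- vapply(parts, `[[`, "", 2L)
  dl <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else "", "")
  out <- list()
  for (s in unique(sp)) {
    idx <- sp == s
    doms <- lapply(dl[idx], function(x) {
      v <- strsplit(x, ",", fixed = TRUE)[[1]]
      v[nzchar(trimws(v))]
    })
    names(doms) <- pr[idx]
    out[[s]] <- domain_assignments(s, doms)
  }
  out
}

#' Write domain assignment tables as TSV
#'
#' @param assignments a `domain_assignments` object or a list of them.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_assignments_tsv <- function(assignments, path) {
  if (inherits(assignments, "domain_assignments"))
    assignments <- list(assignments)
  rows <- do.call(rbind, lapply(assignments, function(a) {
    data.frame(species = a$species,
               protein = names(a$proteins),
               domains = vapply(a$proteins, paste, "", collapse = ","))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a domain co-occurrence network
#'
#' Every distinct domain family observed in the proteome becomes a node; an
#' (undirected, unweighted) edge joins two distinct families whenever they
#' co-occur within at least one protein. Repeats of a family within one
#' protein do not create self-loops, and multiple co-occurrences collapse to
#' a single edge; the number of supporting proteins is retained as the
#' `co_occurrences` edge attribute but plays no role in scoring.
#'
#' @param assignments a `domain_assignments` object.
#' @return object of class `domain_network`: list with `species` and an
#'   igraph `graph`.
#' @export
build_dcn <- function(assignments) {
  stopifnot(inherits(assignments, "domain_assignments"))
  nodes <- sort(unique(unlist(assignments$proteins, use.names = FALSE)))
  pair_list <- lapply(assignments$proteins, function(doms) {
    doms <- sort(unique(doms))
    if (length(doms) < 2) return(NULL)
    t(utils::combn(doms, 2))
  })
  pairs <- do.call(rbind, pair_list)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
    counts <- table(key)
    uniq <- !duplicated(key)
    g <- igraph::add_edges(g, t(pairs[uniq, , drop = FALSE]))
    igraph::E(g)$co_occurrences <- as.integer(counts[key[uniq]])
  }
  structure(list(species = assignments$species, graph = g),
            class = "domain_network")
}

#' @export
print.domain_network <- function(x, ...) {
  cat("domain_network for species", x$species, "with",
      igraph::vcount(x$graph), "domain families and",
      igraph::ecount(x$graph), "co-occurrence edges\n")
  invisible(x)
}

#' Select the most closely related species from species-tagged hits
#'
#' The species of the profile-sequence hit with the smallest e-value is
#' taken as the most closely related organism; its pre-built DCN is the one
#' used for network-based prediction. Ties at the minimum e-value are broken
#' by the lexicographically smallest species id.
#'
#' @param hits a [homology_hits] frame with `source = "psiblast"` and
#'   populated species tags.
#' @return a species id.
#' @export
select_species <- function(hits) {
  hits <- hits[!is.na(hits$species), , drop = FALSE]
  if (nrow(hits) == 0)
    stop("no species-tagged hits: no co-occurrence network applicable")
  stopifnot(all(hits$source == "psiblast"))
  best <- hits$species[hits$evalue == min(hits$evalue)]
  sort(best)[[1]]
}

#' Neighboring domain families within a given radius
#'
#' Returns the domain families at shortest-path distance between 1 and
#' `radius` (inclusive) from any center — i.e. direct neighbors for
#' radius 1, and neighbors-of-neighbors as well for radius 2. The centers
#' themselves are always excluded: function is transferred *from* neighbors
#' precisely because the centers are uninformative.
#'
#' @param network a `domain_network`.
#' @param centers character vector of domain families, all present in the
#'   network (callers intersect detected domains with the node set first).
#' @param radius 1 or 2.
#' @return character vector of neighboring domain families.
#' @export
neighbor_set <- function(network, centers, radius = 1) {
  stopifnot(inherits(network, "domain_network"), radius %in% c(1, 2))
  nodes <- igraph::V(network$graph)$name
  missing <- setdiff(centers, nodes)
  if (length(missing) > 0)
    stop("center domain(s) not in network: ", paste(missing, collapse = ", "))
  if (length(centers) == 0) return(character())
  d <- igraph::distances(network$graph, v = centers)
  dmin <- apply(d, 2, min)
  sort(nodes[dmin >= 1 & dmin <= radius])
}

#' Level-3 prediction by aggregated neighbor-counting
#'
#' Gathers the GO annotations of the radius-one neighbors of the center
#' domains in the species DCN. If no radius-one neighbor carries any GO
#' term, the search falls back to the domains at distance exactly two. For
#' each distinct GO term `g`, its occurrence frequency is
#' `f(g) = (# neighbor domains annotated with g) / (total number of
#' (domain, GO term) occurrences over all neighbor domains)`, and the
#' confidence is `S = 0.3 * f(g)`, so all confidences lie in (0, 0.3\] and
#' sum to exactly 0.3. The counting unit is the neighbor domain: duplicate
#' annotation rows of one domain count once.
#'
#' @param network a `domain_network`.
#' @param centers character vector of center domain families (already
#'   intersected with the network's node set; non-empty).
#' @param domain_annotations an `annotation_map` from domain families to GO
#'   terms.
#' @param target optional target id to stamp on the predictions.
#' @return prediction data frame (level = 3); empty if neither radius yields
#'   any annotated neighbor.
#' @export
neighbor_counting_predict <- function(network, centers, domain_annotations,
                                      target = NA_character_) {
  if (length(centers) == 0) stop("no center domains")
  n1 <- neighbor_set(network, centers, radius = 1)
  ann <- lapply(n1, annotation_of, map = domain_annotations)
  names(ann) <- n1
  if (sum(lengths(ann)) == 0) {
    # fallback: only the domains at distance exactly 2
    n2 <- setdiff(neighbor_set(network, centers, radius = 2), n1)
    ann <- lapply(n2, annotation_of, map = domain_annotations)
    names(ann) <- n2
  }
  ann <- ann[lengths(ann) > 0]
  if (length(ann) == 0) return(empty_predictions())
  occurrences <- unlist(lapply(ann, unique), use.names = FALSE)
  counts <- table(occurrences)
  f <- as.numeric(counts) / length(occurrences)
  prediction_frame(target = target, term = names(counts),
                   confidence = 0.3 * f, level = 3L)
}

#' Write a domain network as an edge-list TSV
#'
#' Two columns (the endpoint families), one row per co-occurrence edge.
#' Isolated nodes are listed afterwards as single-column rows so the node
#' set round-trips.
#'
#' @param network a `domain_network`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_dcn_tsv <- function(network, path) {
  el <- igraph::as_edgelist(network$graph)
  iso <- setdiff(igraph::V(network$graph)$name, as.vector(el))
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(el) > 0)
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  if (length(iso) > 0) writeLines(iso, con)
  invisible(path)
}

#' Write a domain network as GraphML
#'
#' @param network a `domain_network`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_dcn_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
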