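# Homology-search hit tables and the level-1 (profile-sequence) and level-2
# (profile-profile) prediction steps.

#' Construct a table of homology-search hits
#'
#' A hit table is an ordinary data frame with one row per hit and columns
#' `query`, `subject`, `species`, `evalue`, `probability`, `source`. Exactly
#' one of `evalue` / `probability` is populated per row, matching the source:
#' profile-sequence hits (`source = "psiblast"`) carry an e-value >= 0;
#' profile-profile hits (`source = "hhsearch"`) carry a probability score in
#' \[0, 100\].
#'
#' @param query character vector of target protein ids.
#' @param subject character vector of database protein or domain-family ids.
#' @param source `"psiblast"` or `"hhsearch"` (scalar or vector).
#' @param evalue numeric e-values (NA for hhsearch rows).
#' @param probability numeric probabilities in \[0, 100\] (NA for psiblast
#'   rows).
#' @param species optional character vector of species tags of subjects.
#' @return data frame of class `homology_hits`.
#' @export
homology_hits <- function(query, subject, source,
                          evalue = NA_real_, probability = NA_real_,
                          species = NA_character_) {
  n <- length(query)
  if (n == 0) {
    evalue <- numeric(); probability <- numeric(); species <- character()
    source <- character()
  }
  df <- data.frame(query = as.character(query),
                   subject = as.character(subject),
                   species = as.character(species),
                   evalue = as.numeric(evalue),
                   probability = as.numeric(probability),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_hits(df)
  class(df) <- c("homology_hits", "data.frame")
  df
}

validate_hits <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$source %in% c("psiblast", "hhsearch")))
    stop("source must be 'psiblast' or 'hhsearch'")
  psi <- df$source == "psiblast"
  if (any(is.na(df$evalue[psi])) || any(!is.na(df$probability[psi])))
    stop("psiblast hits must populate evalue and not probability")
  if (any(df$evalue[psi] < 0)) stop("negative e-value")
  hh <- !psi
  if (any(is.na(df$probability[hh])) || any(!is.na(df$evalue[hh])))
    stop("hhsearch hits must populate probability and not evalue")
  if (any(df$probability[hh] < 0 | df$probability[hh] > 100))
    stop("probability outside [0, 100]")
  invisible(df)
}

empty_hits <- function() {
  homology_hits(character(), character(), character())
}

#' Parse BLAST tabular output (outfmt 6 / -m 8)
#'
#' Reads the standard 12-column tab-separated hit table (query, subject,
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore). A subject of the form `"species|accession"` is
#' split into a species tag and the bare accession. Duplicate
#' (query, subject) pairs are collapsed, keeping the best (minimum) e-value;
#' otherwise rows are preserved in file order.
#'
#' @param path path to a file, or a character vector of lines.
#' @return a [homology_hits] data frame with `source = "psiblast"`.
#' @export
parse_blast_tabular <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("line ", which(nf < 12)[1], ": expected 12 tab-separated columns")
  qry <- vapply(fields, `[[`, "", 1L)
  sbj <- vapply(fields, `[[`, "", 2L)
  ev_chr <- vapply(fields, `[[`, "", 11L)
  ev <- suppressWarnings(as.numeric(ev_chr))
  if (anyNA(ev))
    stop("line ", which(is.na(ev))[1], ": non-numeric e-value '",
         ev_chr[which(is.na(ev))[1]], "'")

  species <- rep(NA_character_, length(sbj))
  piped <- grepl("|", sbj, fixed = TRUE)
  species[piped] <- sub("\\|.*$", "", sbj[piped])
  sbj[piped] <- sub("^[^|]*\\|", "", sbj[piped])

  hits <- homology_hits(qry, sbj, "psiblast", evalue = ev, species = species)
  dedup_best_evalue(hits)
}

# collapse duplicate (query, subject) pairs to the minimum e-value, keeping
# the order of first appearance
dedup_best_evalue <- function(hits) {
  key <- paste(hits$query, hits$subject, sep = "\r")
  if (!anyDuplicated(key)) return(hits)
  best <- tapply(hits$evalue, key, min)
  first <- !duplicated(key)
  out <- hits[first, , drop = FALSE]
  out$evalue <- unname(best[key[first]])
  rownames(out) <- NULL
  out
}

#' Parse HHSearch domain-detection output
#'
#' Accepts either a `.hhr` file (only the summary table is read: columns
#' `No`, `Hit`, `Prob`, ...; the query id is taken from the `Query` header
#' line) or a simplified 3-column TSV with columns query, domain family,
#' probability.
#'
#' @param path path to a file, or a character vector of lines.
#' @param query query id to use for hhr input lacking a `Query` header.
#' @return a [homology_hits] data frame with `source = "hhsearch"`.
#' @export
parse_hhsearch_hits <- function(path, query = NA_character_) {
  lines <- read_input_lines(path)
  header_idx <- grep("^\\s*No\\s+Hit", lines)
  if (length(header_idx) > 0) {
    qline <- grep("^Query\\s", lines, value = TRUE)
    if (length(qline) > 0)
      query <- strsplit(trimws(sub("^Query\\s+", "", qline[[1]])), "\\s+")[[1]][1]
    body <- lines[(header_idx[[1]] + 1L):length(lines)]
    rows <- grep("^\\s*\\d+\\s+\\S", body, value = TRUE)
    stop_at <- which(!nzchar(trimws(body)))
    if (length(stop_at) > 0)
      rows <- grep("^\\s*\\d+\\s+\\S", body[seq_len(stop_at[[1]] - 1L)],
                   value = TRUE)
    if (length(rows) == 0) return(empty_hits())
    parts <- strsplit(trimws(rows), "\\s+")
    dom <- vapply(parts, `[[`, "", 2L)
    prob <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(prob)) stop("could not parse Prob column of hhr summary table")
  } else {
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    if (length(lines) == 0) return(empty_hits())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
      stop("line ", which(nf < 3)[1],
           ": expected 3 tab-separated columns (query, domain, probability)")
    query <- vapply(parts, `[[`, "", 1L)
    dom <- vapply(parts, `[[`, "", 2L)
    prob <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(prob))
      stop("line ", which(is.na(prob))[1], ": non-numeric probability")
  }
  if (any(prob < 0 | prob > 100))
    stop("probability outside [0, 100]")
  homology_hits(query, dom, "hhsearch", probability = prob)
}

read_input_lines <- function(path) {
  if (length(path) == 0) return(character())
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path)
  else as.character(unlist(strsplit(path, "\n", fixed = TRUE)))
}

#' Read an entity-to-GO annotation map
#'
#' Reads a 2-column TSV (entity id, GO term id) into a named list mapping
#' each entity to its set of GO terms. Entities listed with an empty term
#' field keep an empty set — unannotated Pfam domains are meaningful in the
#' network predictions.
#'
#' @param path path to a file, or a character vector of lines.
#' @return named list of character vectors (class `annotation_map`).
#' @export
read_annotation_tsv <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(annotation_map(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ent <- vapply(parts, `[[`, "", 1L)
  trm <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "", "")
  m <- tapply(trm, ent, function(x) unique(x[nzchar(x)]), simplify = FALSE)
  annotation_map(lapply(m, as.character))
}

#' Read protein GO annotations from a GAF 2.x file
#'
#' Consumes columns 2 (DB object id) and 5 (GO id) of a Gene Association
#' File; comment lines starting with `!` are skipped.
#'
#' @param path path to a file, or a character vector of lines.
#' @return an `annotation_map` (named list of GO term sets).
#' @export
read_gaf <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "!")]
  if (length(lines) == 0) return(annotation_map(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5))
    stop("line ", which(nf < 5)[1], ": GAF record has fewer than 5 columns")
  ent <- vapply(parts, `[[`, "", 2L)
  trm <- vapply(parts, `[[`, "", 5L)
  m <- tapply(trm, ent, function(x) unique(x[nzchar(x)]), simplify = FALSE)
  annotation_map(lapply(m, as.character))
}

#' Construct an annotation map
#'
#' @param x named list mapping entity ids to character vectors of GO terms.
#'   Empty sets are permitted.
#' @return the list with class `annotation_map`.
#' @export
annotation_map <- function(x) {
  if (length(x) > 0 && is.null(names(x)))
    stop("annotation map must be named by entity id")
  x <- lapply(x, as.character)
  class(x) <- "annotation_map"
  x
}

#' Write an annotation map as 2-column TSV
#'
#' @param map an `annotation_map`.
#' @param path output file path. Entities with empty annotation sets are
#'   written as a single row with an empty term field so they round-trip.
#' @return invisibly, `path`.
#' @export
write_annotation_tsv <- function(map, path) {
  ent <- rep(names(map), pmax(lengths(map), 1L))
  trm <- unlist(lapply(map, function(x) if (length(x) == 0) "" else x),
                use.names = FALSE)
  utils::write.table(data.frame(ent, trm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

annotation_of <- function(map, entity) {
  if (is.null(map) || !(entity %in% names(map))) character()
  else map[[entity]]
}

#' Confidence score for a profile-sequence (PSI-BLAST) hit
#'
#' `S = 0.6 + 0.4 * (-log10(e)) / 200`, capped above at 1.0. An e-value of 0
#' (or below machine-tiny) maps to 1.0. With `floor = TRUE` (the default,
#' used for genuine level-1 predictions) the score is also floored at 0.6,
#' giving the level-1 range \[0.6, 1\]. With `floor = FALSE` the raw formula
#' value is clipped only to (0, 1\]; hits weaker than the level-1 e-value
#' cutoff then score just below 0.6, ranking them under genuine level-1
#' predictions (used for hard-case fallback hits).
#'
#' @param evalue numeric vector of e-values >= 0.
#' @param floor apply the 0.6 lower bound (default TRUE).
#' @param log_base base of the logarithm in the formula; 10 by default.
#' @return numeric vector of confidence scores.
#' @export
score_psiblast <- function(evalue, floor = TRUE, log_base = 10) {
  evalue <- as.numeric(evalue)
  if (any(is.na(evalue))) stop("missing e-value")
  if (any(evalue < 0)) stop("negative e-value")
  zero <- evalue < .Machine$double.xmin
  s <- rep(1.0, length(evalue))
  s[!zero] <- 0.6 + 0.4 * (-log(evalue[!zero], base = log_base)) / 200
  s <- pmin(s, 1.0)
  if (floor) s <- pmax(s, 0.6)
  pmax(s, .Machine$double.xmin)  # keep scores in (0, 1]
}

#' Confidence score for a profile-profile (HHSearch) hit
#'
#' `S = 0.3 + 0.3 * p / 100` for a probability score `p` in \[0, 100\],
#' giving the level-2 range \[0.3, 0.6\].
#'
#' @param probability numeric vector of probability scores in \[0, 100\].
#' @return numeric vector of confidence scores.
#' @export
score_hhsearch <- function(probability) {
  probability <- as.numeric(probability)
  if (any(is.na(probability))) stop("missing probability")
  if (any(probability < 0 | probability > 100))
    stop("probability outside [0, 100]")
  0.3 + 0.3 * probability / 100
}

#' Level-1 prediction: GO terms of the top profile-sequence hit
#'
#' Hits are filtered to `evalue <= e_cutoff` and ranked by e-value; only the
#' GO terms of the single best hit are emitted, each scored with
#' [score_psiblast()] of that hit's e-value. If several hits tie at the
#' minimum e-value their GO term sets are merged (same score). Returns an
#' empty prediction frame when no hit passes the cutoff or the top hit's
#' subject has no annotations — the signal that a target is a hard case.
#'
#' @param hits a [homology_hits] frame, all rows `source = "psiblast"` and a
#'   single query.
#' @param annotations an `annotation_map` from subject protein ids to GO
#'   terms.
#' @param e_cutoff e-value inclusion threshold (default 0.01).
#' @return prediction data frame (target, term, confidence, level = 1).
#' @export
level1_predict <- function(hits, annotations, e_cutoff = 0.01) {
  if (nrow(hits) == 0) return(empty_predictions())
  stopifnot(all(hits$source == "psiblast"))
  if (length(unique(hits$query)) > 1)
    stop("level1_predict expects hits of a single query")
  hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_predictions())
  best_e <- min(hits$evalue)
  top <- hits[hits$evalue == best_e, , drop = FALSE]
  terms <- unique(unlist(lapply(top$subject, annotation_of, map = annotations),
                         use.names = FALSE))
  if (length(terms) == 0) return(empty_predictions())
  prediction_frame(target = hits$query[[1]], term = terms,
                   confidence = score_psiblast(best_e), level = 1L)
}

#' Level-2 prediction: GO terms of detected domain families
#'
#' Profile-profile hits with probability >= `p_cutoff` are retained; each
#' retained domain family contributes its annotated GO terms, scored with
#' [score_hhsearch()] of the domain's probability. A GO term contributed by
#' several domains keeps the maximum confidence.
#'
#' @param hits a [homology_hits] frame, all rows `source = "hhsearch"` and a
#'   single query.
#' @param domain_annotations an `annotation_map` from domain-family ids to GO
#'   terms.
#' @param p_cutoff probability retention threshold (default 80).
#' @return list with `predictions` (prediction frame, level = 2) and
#'   `detected_domains` (character vector of retained domain families).
#' @export
level2_predict <- function(hits, domain_annotations, p_cutoff = 80) {
  if (nrow(hits) == 0)
    return(list(predictions = empty_predictions(),
                detected_domains = character()))
  stopifnot(all(hits$source == "hhsearch"))
  if (length(unique(hits$query)) > 1)
    stop("level2_predict expects hits of a single query")
  kept <- hits[hits$probability >= p_cutoff, , drop = FALSE]
  if (nrow(kept) == 0)
    return(list(predictions = empty_predictions(),
                detected_domains = character()))
  # per domain family keep its best probability
  pbest <- tapply(kept$probability, kept$subject, max)
  doms <- names(pbest)
  preds <- empty_predictions()
  for (d in doms) {
    terms <- annotation_of(domain_annotations, d)
    if (length(terms) == 0) next
    preds <- rbind(preds, prediction_frame(
      target = kept$query[[1]], term = terms,
      confidence = score_hhsearch(pbest[[d]]), level = 2L))
  }
  preds <- merge_max_confidence(preds)
  list(predictions = preds, detected_domains = unname(doms))
}
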