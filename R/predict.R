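# The three predictor strategies, prediction finalization and CAFA-format
# output.

#' Construct a prediction frame
#'
#' Predictions are plain data frames with columns `target`, `term`,
#' `confidence` (in (0, 1\]) and `level` (1 = profile-sequence,
#' 2 = profile-profile, 3 = co-occurrence network, 0 = frequency-based
#' scoring of the pooled predictors).
#'
#' @param target target protein id.
#' @param term GO term ids.
#' @param confidence numeric confidences in (0, 1].
#' @param level provenance level (0, 1, 2 or 3).
#' @return data frame of class `prediction_frame`.
#' @export
prediction_frame <- function(target, term, confidence, level) {
  df <- data.frame(target = as.character(target),
                   term = as.character(term),
                   confidence = as.numeric(confidence),
                   level = as.integer(level),
                   stringsAsFactors = FALSE)
  class(df) <- c("prediction_frame", "data.frame")
  df
}

#' @rdname prediction_frame
#' @export
empty_predictions <- function() {
  prediction_frame(character(), character(), numeric(), integer())
}

# Duplicate GO terms keep the row with maximum confidence (ties: lowest
# level, then first occurrence).
merge_max_confidence <- function(preds) {
  if (nrow(preds) <= 1) return(preds)
  ord <- order(preds$term, -preds$confidence, preds$level)
  preds <- preds[ord, , drop = FALSE]
  preds <- preds[!duplicated(preds$term), , drop = FALSE]
  rownames(preds) <- NULL
  preds
}

#' Thresholds and parameters of the predictors
#'
#' @param e_cutoff level-1 e-value inclusion threshold (default 0.01).
#' @param default_e the search tool's default e-value threshold used for
#'   fallback searches on hard cases and for predictor 3 (default 10).
#' @param p_cutoff level-2 probability retention threshold (default 80).
#' @param weights per-source weights of predictor 2's weighted GO-term
#'   frequency (profile-sequence 4, profile-profile 2, network 1).
#' @param max_predictions cap on predictions per target (default 100).
#' @return a named list of class `funclevels_config`.
#' @export
funclevels_config <- function(e_cutoff = 0.01, default_e = 10, p_cutoff = 80,
                              weights = c(psiblast = 4, hhsearch = 2, dcn = 1),
                              max_predictions = 100) {
  stopifnot(e_cutoff > 0, default_e > 0, p_cutoff >= 0, p_cutoff <= 100,
            length(weights) == 3, all(weights > 0), max_predictions >= 1)
  names(weights) <- c("psiblast", "hhsearch", "dcn")
  structure(list(e_cutoff = e_cutoff, default_e = default_e,
                 p_cutoff = p_cutoff, weights = weights,
                 max_predictions = max_predictions),
            class = "funclevels_config")
}

#' Finalize a target's prediction list
#'
#' Merges duplicate GO terms keeping the maximum confidence, clips
#' confidences into (0, 1\], sorts by confidence descending (ties by GO id
#' ascending) and truncates to `max_predictions` rows. When a tie group
#' straddles the cap, the group is truncated internally in GO-id order.
#'
#' @param preds a prediction frame for one target.
#' @param max_predictions maximum rows to keep (default 100).
#' @return the finalized prediction frame.
#' @export
finalize <- function(preds, max_predictions = 100) {
  if (nrow(preds) == 0) return(preds)
  preds <- merge_max_confidence(preds)
  preds$confidence <- pmin(preds$confidence, 1.0)
  preds <- preds[preds$confidence > 0, , drop = FALSE]
  preds <- preds[order(-preds$confidence, preds$term), , drop = FALSE]
  preds <- utils::head(preds, max_predictions)
  rownames(preds) <- NULL
  preds
}

# Shared hard-case machinery: score default-threshold profile-sequence hits
# with the unfloored level-1 formula, and run neighbor-counting on the DCN of
# the most closely related species with all detected domains as centers.
hard_case_predict <- function(target, fallback_hits, hhsearch_hits,
                              annotations, domain_annotations, networks,
                              species_hits, config) {
  preds <- empty_predictions()
  if (nrow(fallback_hits) > 0) {
    fb <- fallback_hits[fallback_hits$evalue <= config$default_e, ,
                        drop = FALSE]
    for (i in seq_len(nrow(fb))) {
      terms <- annotation_of(annotations, fb$subject[[i]])
      if (length(terms) == 0) next
      preds <- rbind(preds, prediction_frame(
        target = target, term = terms,
        confidence = score_psiblast(fb$evalue[[i]], floor = FALSE),
        level = 1L))
    }
  }
  sp_hits <- species_hits[!is.na(species_hits$species), , drop = FALSE]
  centers_all <- unique(hhsearch_hits$subject)
  if (nrow(sp_hits) > 0 && length(centers_all) > 0 && length(networks) > 0) {
    sp <- select_species(sp_hits)
    net <- networks[[sp]]
    if (is.null(net)) {
      message("target ", target, ": no network for species ", sp)
    } else {
      nodes <- igraph::V(net$graph)$name
      centers <- intersect(centers_all, nodes)
      dropped <- setdiff(centers_all, nodes)
      if (length(dropped) > 0)
        message("target ", target, ": domain(s) absent from ", sp,
                " network dropped: ", paste(dropped, collapse = ", "))
      if (length(centers) > 0)
        preds <- rbind(preds, neighbor_counting_predict(
          net, centers, domain_annotations, target = target))
    }
  }
  preds
}

#' Predictor 1: sequential three-level prediction
#'
#' The main predictor combines the three levels hierarchically. Level 1
#' transfers the GO terms of the top profile-sequence hit (e-value <=
#' `e_cutoff`), scored in \[0.6, 1\]; level 2 adds the annotations of domain
#' families detected by profile-profile search (probability >= `p_cutoff`),
#' scored in \[0.3, 0.6\]. A target for which both levels come up empty is a
#' hard case: default-threshold fallback hits are scored by the unfloored
#' level-1 formula, and aggregated neighbor-counting is run on the
#' co-occurrence network of the most closely related species, using all
#' detected domains (any probability) as centers, scoring in (0, 0.3\].
#' Duplicate GO terms keep the maximum confidence; the result is finalized.
#'
#' @param target target protein id.
#' @param psiblast_hits profile-sequence hits for this target.
#' @param hhsearch_hits profile-profile hits for this target.
#' @param fallback_hits default-threshold profile-sequence hits (hard cases).
#' @param annotations protein `annotation_map`.
#' @param domain_annotations domain-family `annotation_map`.
#' @param networks named list of `domain_network` objects, keyed by species.
#' @param species_hits species-tagged profile-sequence hits used to pick the
#'   network species; defaults to `fallback_hits`.
#' @param config a [funclevels_config()].
#' @return a finalized prediction frame (possibly empty).
#' @export
predictor1 <- function(target, psiblast_hits = empty_hits(),
                       hhsearch_hits = empty_hits(),
                       fallback_hits = empty_hits(),
                       annotations = annotation_map(list()),
                       domain_annotations = annotation_map(list()),
                       networks = list(),
                       species_hits = fallback_hits,
                       config = funclevels_config()) {
  l1 <- level1_predict(psiblast_hits, annotations, config$e_cutoff)
  l2 <- level2_predict(hhsearch_hits, domain_annotations, config$p_cutoff)
  preds <- rbind(l1, l2$predictions)
  if (nrow(preds) == 0) {
    message("target ", target, ": hard case (levels 1-2 empty)")
    preds <- hard_case_predict(target, fallback_hits, hhsearch_hits,
                               annotations, domain_annotations, networks,
                               species_hits, config)
  }
  if (nrow(preds) == 0) {
    message("target ", target, ": no predictions")
    return(empty_predictions())
  }
  finalize(preds, config$max_predictions)
}

#' Predictor 2: weighted GO-term frequency across the three sources
#'
#' GO-term occurrences are pooled from (a) every profile-sequence hit with
#' e-value <= `e_cutoff` (one count per hit whose subject carries the term),
#' (b) every domain family detected at probability >= `p_cutoff`, and (c)
#' the radius-one neighbor domains of those detected families in the
#' species DCN. The weighted frequency `W(g) = 4 n_psi(g) + 2 n_hh(g) +
#' n_dcn(g)` is normalized by its maximum, so the best-supported term scores
#' exactly 1. If no source fires, the GO terms of the default-threshold
#' fallback hits are scored by their plain occurrence frequency.
#'
#' @inheritParams predictor1
#' @return a finalized prediction frame (level = 0).
#' @export
predictor2 <- function(target, psiblast_hits = empty_hits(),
                       hhsearch_hits = empty_hits(),
                       fallback_hits = empty_hits(),
                       annotations = annotation_map(list()),
                       domain_annotations = annotation_map(list()),
                       networks = list(),
                       species_hits = fallback_hits,
                       config = funclevels_config()) {
  counts <- c(psiblast = 0, hhsearch = 0, dcn = 0)  # structure documentation
  tally <- function(term_sets) {
    occ <- unlist(lapply(term_sets, unique), use.names = FALSE)
    if (length(occ) == 0) return(numeric())
    tab <- table(occ)
    stats::setNames(as.numeric(tab), names(tab))
  }

  psi <- psiblast_hits[psiblast_hits$evalue <= config$e_cutoff, , drop = FALSE]
  n_psi <- tally(lapply(psi$subject, annotation_of, map = annotations))

  kept <- hhsearch_hits[hhsearch_hits$probability >= config$p_cutoff, ,
                        drop = FALSE]
  doms <- unique(kept$subject)
  n_hh <- tally(lapply(doms, annotation_of, map = domain_annotations))

  n_dcn <- numeric()
  sp_hits <- species_hits[!is.na(species_hits$species), , drop = FALSE]
  if (length(doms) > 0 && nrow(sp_hits) > 0 && length(networks) > 0) {
    sp <- select_species(sp_hits)
    net <- networks[[sp]]
    if (!is.null(net)) {
      centers <- intersect(doms, igraph::V(net$graph)$name)
      if (length(centers) > 0) {
        nbrs <- neighbor_set(net, centers, radius = 1)
        n_dcn <- tally(lapply(nbrs, annotation_of, map = domain_annotations))
      }
    }
  }

  terms <- unique(c(names(n_psi), names(n_hh), names(n_dcn)))
  if (length(terms) > 0) {
    w <- config$weights
    W <- w[["psiblast"]] * vapply(terms, function(g) sum(n_psi[g], na.rm = TRUE), 1) +
         w[["hhsearch"]] * vapply(terms, function(g) sum(n_hh[g], na.rm = TRUE), 1) +
         w[["dcn"]]      * vapply(terms, function(g) sum(n_dcn[g], na.rm = TRUE), 1)
    preds <- prediction_frame(target = target, term = terms,
                              confidence = W / max(W), level = 0L)
    return(finalize(preds, config$max_predictions))
  }

  # fallback: plain GO-term frequency over default-threshold hits
  fb <- fallback_hits[fallback_hits$evalue <= config$default_e, , drop = FALSE]
  preds <- frequency_predict(target, fb, annotations)
  if (nrow(preds) == 0) {
    message("target ", target, ": no predictions")
    return(empty_predictions())
  }
  finalize(preds, config$max_predictions)
}

# occurrence frequency of each GO term among annotated hits
frequency_predict <- function(target, hits, annotations) {
  sets <- lapply(hits$subject, annotation_of, map = annotations)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) return(empty_predictions())
  occ <- unlist(lapply(sets, unique), use.names = FALSE)
  tab <- table(occ)
  prediction_frame(target = target, term = names(tab),
                   confidence = as.numeric(tab) / length(sets), level = 0L)
}

#' Predictor 3: GO-term frequency over all default-threshold hits
#'
#' Pools every profile-sequence hit found at the search tool's default
#' e-value threshold; the confidence of a GO term is the fraction of
#' annotated hits whose subject carries it, so a term present on every
#' annotated hit scores 1.
#'
#' @param target target protein id.
#' @param psiblast_hits_default profile-sequence hits searched at the
#'   default threshold.
#' @param annotations protein `annotation_map`.
#' @param config a [funclevels_config()].
#' @return a finalized prediction frame (level = 0).
#' @export
predictor3 <- function(target, psiblast_hits_default = empty_hits(),
                       annotations = annotation_map(list()),
                       config = funclevels_config()) {
  hits <- psiblast_hits_default[
    psiblast_hits_default$evalue <= config$default_e, , drop = FALSE]
  preds <- frequency_predict(target, hits, annotations)
  if (nrow(preds) == 0) return(empty_predictions())
  finalize(preds, config$max_predictions)
}

#' Run a predictor over a set of targets
#'
#' Convenience driver: slices per-target hit tables out of pooled ones and
#' applies the chosen predictor, returning one combined prediction frame.
#'
#' @param targets character vector of target ids.
#' @param predictor 1, 2 or 3.
#' @param psiblast_hits,hhsearch_hits,fallback_hits pooled hit tables (the
#'   `query` column selects each target's rows).
#' @param annotations,domain_annotations annotation maps.
#' @param networks named list of `domain_network`s by species.
#' @param config a [funclevels_config()].
#' @return a prediction frame covering all targets.
#' @export
predict_targets <- function(targets, predictor = 1,
                            psiblast_hits = empty_hits(),
                            hhsearch_hits = empty_hits(),
                            fallback_hits = empty_hits(),
                            annotations = annotation_map(list()),
                            domain_annotations = annotation_map(list()),
                            networks = list(),
                            config = funclevels_config()) {
  stopifnot(predictor %in% 1:3)
  out <- empty_predictions()
  for (tg in targets) {
    psi <- psiblast_hits[psiblast_hits$query == tg, , drop = FALSE]
    hh <- hhsearch_hits[hhsearch_hits$query == tg, , drop = FALSE]
    fb <- fallback_hits[fallback_hits$query == tg, , drop = FALSE]
    entry <- switch(as.character(predictor),
      "1" = predictor1(tg, psi, hh, fb, annotations, domain_annotations,
                       networks, fb, config),
      "2" = predictor2(tg, psi, hh, fb, annotations, domain_annotations,
                       networks, fb, config),
      "3" = predictor3(tg, fb, annotations, config))
    out <- rbind(out, entry)
  }
  out
}

#' Write predictions in the CAFA 3-column format
#'
#' One line per prediction: target, GO term and the confidence formatted to
#' two decimals with a printed floor of 0.01. Rows are ordered by target,
#' then confidence descending, then GO id. The input must be finalized (no
#' duplicate (target, term) pairs).
#'
#' @param predictions a prediction frame.
#' @param path output file path or connection.
#' @return invisibly, the number of lines written.
#' @export
write_cafa <- function(predictions, path) {
  if (anyDuplicated(paste(predictions$target, predictions$term)))
    stop("predictions not finalized: duplicate (target, term) pairs")
  p <- predictions[order(predictions$target, -predictions$confidence,
                         predictions$term), , drop = FALSE]
  lines <- sprintf("%s\t%s\t%.2f", p$target, p$term,
                   pmax(p$confidence, 0.01))
  writeLines(lines, path)
  invisible(length(lines))
}

#' Read predictions from the CAFA 3-column format
#'
#' @param path path to a file, or a character vector of lines.
#' @return a prediction frame (level = 0: provenance is not serialized).
#' @export
read_cafa <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_predictions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("line ", which(nf < 3)[1], ": expected 3 tab-separated columns")
  prediction_frame(
    target = vapply(parts, `[[`, "", 1L),
    term = vapply(parts, `[[`, "", 2L),
    confidence = as.numeric(vapply(parts, `[[`, "", 3L)),
    level = 0L)
}
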