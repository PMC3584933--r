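# Independent brute-force oracles. These work on plain base-R structures
# (a parents list, an edge matrix, data frames) with explicit set
# arithmetic, sharing no code with the package implementation.

# ancestor closure (including self) by naive recursive climb
oracle_ancestors <- function(parents, term) {
  res <- term
  for (p in parents[[term]]) res <- union(res, oracle_ancestors(parents, p))
  res
}

oracle_propagate <- function(parents, terms) {
  out <- character()
  for (t in terms) out <- union(out, oracle_ancestors(parents, t))
  out
}

oracle_similarity <- function(parents, g1, g2) {
  r1 <- oracle_ancestors(parents, g1)
  r2 <- oracle_ancestors(parents, g2)
  length(intersect(r1, r2)) / max(length(r1), length(r2))
}

# all root paths, as lists of node vectors; for depth conventions
oracle_root_paths <- function(parents, term) {
  if (length(parents[[term]]) == 0) return(list(term))
  out <- list()
  for (p in parents[[term]])
    for (path in oracle_root_paths(parents, p))
      out[[length(out) + 1L]] <- c(term, path)
  out
}

oracle_depth <- function(parents, term, convention = "shortest") {
  lens <- lengths(oracle_root_paths(parents, term))
  if (convention == "shortest") min(lens) else max(lens)
}

# BFS distances over an undirected edge matrix (2 columns of node names)
oracle_neighbor_set <- function(nodes, edges, centers, radius) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[centers] <- 0
  frontier <- centers
  d <- 0
  while (length(frontier) > 0 && d < radius) {
    d <- d + 1
    nxt <- character()
    for (v in frontier) for (u in adj[[v]])
      if (dist[[u]] > d) { dist[[u]] <- d; nxt <- union(nxt, u) }
    frontier <- nxt
  }
  sort(names(dist)[dist >= 1 & dist <= radius])
}

# tie-grouped top-n selection on a (term, confidence) data frame
oracle_top_groups <- function(entry, n) {
  lv <- sort(unique(entry$confidence), decreasing = TRUE)
  lv <- lv[seq_len(min(n, length(lv)))]
  entry$term[entry$confidence %in% lv]
}

oracle_pr_target <- function(parents, predicted, truth) {
  if (length(predicted) == 0) return(c(0, 0))
  P <- oracle_propagate(parents, predicted)
  T <- oracle_propagate(parents, truth)
  ok <- length(intersect(P, T))
  c(ok / length(P), ok / length(T))
}

# full curve oracles: predictions as data frame (target, term, confidence),
# truth as named list; targets with empty truth excluded up front
oracle_curve <- function(parents, predictions, truth, grid, mode) {
  targets <- names(truth)[lengths(truth) > 0]
  prec <- rec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pr <- matrix(0, nrow = length(targets), ncol = 2)
    for (j in seq_along(targets)) {
      entry <- predictions[predictions$target == targets[[j]], , drop = FALSE]
      sel <- if (mode == "topn") oracle_top_groups(entry, grid[[i]])
             else entry$term[entry$confidence >= grid[[i]]]
      pr[j, ] <- oracle_pr_target(parents, sel, truth[[targets[[j]]]])
    }
    prec[i] <- mean(pr[, 1]); rec[i] <- mean(pr[, 2])
  }
  data.frame(selector = grid, precision = prec, recall = rec)
}

oracle_break_even <- function(curve) {
  best_gap <- Inf; best <- NULL
  for (i in seq_len(nrow(curve))) {
    gap <- abs(curve$precision[[i]] - curve$recall[[i]])
    if (gap < best_gap ||
        (gap == best_gap && curve$selector[[i]] > best$t)) {
      best_gap <- gap
      best <- list(t = curve$selector[[i]],
                   precision = curve$precision[[i]],
                   recall = curve$recall[[i]])
    }
  }
  best
}

oracle_similarity_curves <- function(parents, predictions, truth, k_range) {
  targets <- names(truth)[lengths(truth) > 0]
  avg <- best <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    pa <- pb <- numeric(length(targets))
    for (j in seq_along(targets)) {
      entry <- predictions[predictions$target == targets[[j]], , drop = FALSE]
      sel <- oracle_top_groups(entry, k_range[[i]])
      if (length(sel) == 0) next
      sims <- numeric(length(sel))
      for (k in seq_along(sel)) {
        s <- 0
        for (tt in truth[[targets[[j]]]])
          s <- max(s, oracle_similarity(parents, sel[[k]], tt))
        sims[[k]] <- s
      }
      pa[[j]] <- mean(sims); pb[[j]] <- max(sims)
    }
    avg[[i]] <- mean(pa); best[[i]] <- mean(pb)
  }
  list(average = avg, best = best)
}
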