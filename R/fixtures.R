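# Synthetic worlds: toy ontologies, multi-species proteomes with domain
# assignments, and mock search-hit tables with planted ground truth.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Generate a random toy GO DAG
#'
#' Grows a single-namespace DAG from one root: each new term attaches to
#' between 1 and `branching` already-existing terms as parents, so the
#' result is acyclic by construction and satisfies all [go_dag] invariants.
#' Deterministic for a fixed seed.
#'
#' @param n_terms number of terms including the root (>= 1).
#' @param branching maximum number of parents per term (>= 1).
#' @param seed integer RNG seed.
#' @return a [go_dag] with terms `GO:0000001` (the root) .. `GO:<n>`.
#' @export
make_toy_dag <- function(n_terms, branching = 2, seed = 1) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (branching < 1) stop("branching must be >= 1")
  with_seed(seed, {
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    parents <- vector("list", n_terms)
    names(parents) <- ids
    parents[[1]] <- character()
    if (n_terms > 1) {
      for (i in 2:n_terms) {
        k <- sample.int(branching, 1)
        parents[[i]] <- sample_safe(ids[seq_len(i - 1)], min(k, i - 1))
      }
    }
    go_dag(parents,
           stats::setNames(rep("biological_process", n_terms), ids))
  })
}

#' Parameters of a synthetic world
#'
#' Defaults describe a small but structurally complete benchmark: three
#' species whose proteomes yield connected co-occurrence networks, a
#' 60-term ontology, and a dozen targets split into easy (strong
#' profile-sequence hit), mid (domain detections only) and hard (no usable
#' homology; function reachable only through network neighbors) strata.
#'
#' @param n_go_terms,branching toy ontology size and maximum parents.
#' @param n_species number of species with proteomes and networks.
#' @param n_domains number of domain families (>= 3).
#' @param n_proteins_per_species proteome size per species.
#' @param n_targets number of prediction targets.
#' @param fraction_easy,fraction_mid,fraction_hard stratum fractions
#'   (remainder after easy and mid is hard).
#' @param annotation_density probability that a domain family carries GO
#'   annotations.
#' @param terms_per_entity maximum GO terms per annotated entity.
#' @param easy_e_range,decoy_e_range,weak_e_range e-value sampling ranges
#'   (log-uniform) for the planted top hits, decoy hits and
#'   default-threshold-only hits.
#' @param mid_p_range,hard_p_range probability sampling ranges for domain
#'   detections of mid targets (above the retention cutoff) and hard
#'   targets (below it).
#' @return a named list of class `world_spec`.
#' @export
world_spec <- function(n_go_terms = 60, branching = 2,
                       n_species = 3, n_domains = 30,
                       n_proteins_per_species = 50,
                       n_targets = 12,
                       fraction_easy = 0.5, fraction_mid = 0.25,
                       fraction_hard = 1 - fraction_easy - fraction_mid,
                       annotation_density = 0.6,
                       terms_per_entity = 3,
                       easy_e_range = c(1e-100, 1e-20),
                       decoy_e_range = c(1e-8, 1e-3),
                       weak_e_range = c(0.1, 10),
                       mid_p_range = c(85, 100),
                       hard_p_range = c(40, 79)) {
  spec <- list(n_go_terms = n_go_terms, branching = branching,
               n_species = n_species, n_domains = n_domains,
               n_proteins_per_species = n_proteins_per_species,
               n_targets = n_targets,
               fraction_easy = fraction_easy, fraction_mid = fraction_mid,
               fraction_hard = fraction_hard,
               annotation_density = annotation_density,
               terms_per_entity = terms_per_entity,
               easy_e_range = easy_e_range, decoy_e_range = decoy_e_range,
               weak_e_range = weak_e_range,
               mid_p_range = mid_p_range, hard_p_range = hard_p_range)
  fr <- c(fraction_easy, fraction_mid, fraction_hard)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
    stop("stratum fractions must be non-negative and sum to 1")
  if (n_go_terms < 2) stop("need at least 2 GO terms")
  if (n_domains < 3)
    stop("need at least 3 domain families to plant network structure")
  if (n_species < 1 || n_targets < 1 || n_proteins_per_species < 1)
    stop("counts must be positive")
  structure(spec, class = "world_spec")
}

rlogunif <- function(n, range) {
  exp(stats::runif(n, log(range[[1]]), log(range[[2]])))
}

#' Generate a synthetic world with planted truth
#'
#' Builds every input the predictors consume: a toy ontology, per-species
#' domain assignment tables and co-occurrence networks, protein and domain
#' annotation maps, per-target profile-sequence / profile-profile /
#' default-threshold hit tables, and a ground-truth annotation map. Truth is
#' planted so that each stratum exercises one level of the architecture:
#'
#' * *easy* targets have a dominant profile-sequence hit whose subject is
#'   annotated with exactly the target's true terms (plus weaker decoys);
#' * *mid* targets have no profile-sequence hits but detected domain
#'   families (probability above the retention cutoff) whose annotations
#'   are the true terms;
#' * *hard* targets have only a weak, species-tagged default-threshold hit
#'   to an unannotated subject and a sub-cutoff domain detection of an
#'   unannotated family; their true terms live exclusively on that family's
#'   radius-one network neighbors.
#'
#' Every species' proteome contains one planted protein carrying the hard
#' center family together with two annotated neighbor families, so the hard
#' stratum is feasible in every network. Regeneration with the same seed and
#' spec is identical.
#'
#' @param spec a [world_spec()].
#' @param seed integer RNG seed.
#' @return object of class `synthetic_world`: list with `dag`, `domains`,
#'   `assignments`, `networks`, `protein_annotations`,
#'   `domain_annotations`, `psiblast_hits`, `hhsearch_hits`,
#'   `fallback_hits`, `truth`, `strata`, `targets`, `seed`, `spec`.
#' @export
make_world <- function(spec = world_spec(), seed = 1) {
  stopifnot(inherits(spec, "world_spec"))
  dag <- make_toy_dag(spec$n_go_terms, spec$branching, seed = seed + 1L)
  with_seed(seed, {
    non_root <- setdiff(dag$terms, dag$roots)
    pick_terms <- function()
      sample_safe(non_root, sample.int(min(spec$terms_per_entity,
                                           length(non_root)), 1))

    domains <- sprintf("PF%05d", seq_len(spec$n_domains))
    hard_center <- domains[[1]]
    hard_neighbors <- domains[2:3]

    # domain annotations: density-thinned, with the planted structure forced
    domain_annotations <- stats::setNames(
      vector("list", spec$n_domains), domains)
    for (d in domains) {
      domain_annotations[[d]] <-
        if (stats::runif(1) <= spec$annotation_density) pick_terms()
        else character()
    }
    domain_annotations[[hard_center]] <- character()
    for (d in hard_neighbors)
      if (length(domain_annotations[[d]]) == 0)
        domain_annotations[[d]] <- pick_terms()
    domain_annotations <- annotation_map(domain_annotations)

    # species proteomes; the planted star protein is in every proteome
    species <- sprintf("sp%02d", seq_len(spec$n_species))
    assignments <- list()
    for (s in species) {
      prots <- list()
      prots[[paste0(s, "_P0001")]] <- c(hard_center, hard_neighbors)
      extra <- setdiff(domains, hard_center)  # keep the planted neighborhood
      for (i in seq_len(spec$n_proteins_per_species - 1L)) {
        prots[[sprintf("%s_P%04d", s, i + 1L)]] <-
          sample_safe(extra, sample.int(min(3, length(extra)), 1))
      }
      assignments[[s]] <- domain_assignments(s, prots)
    }
    networks <- lapply(assignments, build_dcn)

    n <- spec$n_targets
    n_easy <- round(spec$fraction_easy * n)
    n_mid <- round(spec$fraction_mid * n)
    n_hard <- n - n_easy - n_mid
    targets <- sprintf("T%05d", seq_len(n))
    strata <- stats::setNames(
      rep(c("easy", "mid", "hard"), c(n_easy, n_mid, n_hard)), targets)

    protein_annotations <- list()
    truth <- stats::setNames(vector("list", n), targets)
    psi <- list(); hh <- list(); weak <- list()
    annotated_domains <- domains[lengths(domain_annotations) > 0]
    if (n_mid > 0 && length(annotated_domains) == 0)
      stop("infeasible spec: mid targets need annotated domain families")

    for (tg in targets) {
      stratum <- strata[[tg]]
      sp <- sample_safe(species, 1)
      if (stratum == "easy") {
        subj <- paste0("DB_", tg, "_TOP")
        terms <- pick_terms()
        protein_annotations[[subj]] <- terms
        truth[[tg]] <- terms
        psi[[length(psi) + 1L]] <- homology_hits(
          tg, subj, "psiblast",
          evalue = rlogunif(1, spec$easy_e_range), species = sp)
        for (k in seq_len(sample.int(2, 1))) {  # weaker decoys
          dsub <- sprintf("DB_%s_D%d", tg, k)
          protein_annotations[[dsub]] <- pick_terms()
          psi[[length(psi) + 1L]] <- homology_hits(
            tg, dsub, "psiblast",
            evalue = rlogunif(1, spec$decoy_e_range),
            species = sample_safe(species, 1))
        }
      } else if (stratum == "mid") {
        doms <- sample_safe(annotated_domains,
                            min(2, length(annotated_domains)))
        for (d in doms)
          hh[[length(hh) + 1L]] <- homology_hits(
            tg, d, "hhsearch",
            probability = stats::runif(1, spec$mid_p_range[[1]],
                                       spec$mid_p_range[[2]]))
        truth[[tg]] <- unique(unlist(domain_annotations[doms],
                                     use.names = FALSE))
      } else {  # hard
        subj <- paste0("DB_", tg, "_WEAK")
        protein_annotations[[subj]] <- character()
        weak[[length(weak) + 1L]] <- homology_hits(
          tg, subj, "psiblast",
          evalue = rlogunif(1, spec$weak_e_range), species = sp)
        hh[[length(hh) + 1L]] <- homology_hits(
          tg, hard_center, "hhsearch",
          probability = stats::runif(1, spec$hard_p_range[[1]],
                                     spec$hard_p_range[[2]]))
        nbrs <- neighbor_set(networks[[sp]], hard_center, radius = 1)
        truth[[tg]] <- unique(unlist(domain_annotations[nbrs],
                                     use.names = FALSE))
      }
    }

    bindhits <- function(lst)
      if (length(lst) == 0) empty_hits() else do.call(rbind, lst)
    psiblast_hits <- bindhits(psi)
    fallback_hits <- rbind(psiblast_hits, bindhits(weak))

    structure(
      list(dag = dag, domains = domains, assignments = assignments,
           networks = networks,
           protein_annotations = annotation_map(protein_annotations),
           domain_annotations = domain_annotations,
           psiblast_hits = psiblast_hits,
           hhsearch_hits = bindhits(hh),
           fallback_hits = fallback_hits,
           truth = annotation_map(truth), strata = strata,
           targets = targets, seed = seed, spec = spec),
      class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$targets), "targets (",
      paste(names(table(x$strata)), table(x$strata), sep = "=",
            collapse = ", "),
      "),", length(x$dag$terms), "GO terms,",
      length(x$networks), "species networks, seed", x$seed, "\n")
  invisible(x)
}

# 12-column BLAST tabular row for a hit table; filler alignment statistics
# are deterministic functions of the e-value.
format_blast_tabular <- function(hits) {
  if (nrow(hits) == 0) return(character())
  subj <- ifelse(is.na(hits$species), hits$subject,
                 paste0(hits$species, "|", hits$subject))
  bits <- sprintf("%.1f", 50 + pmin(500, -log10(hits$evalue + 1e-300)))
  sprintf("%s\t%s\t%s", hits$query,
          paste(subj, "90.0", "100", "5", "1", "1", "100", "1", "100",
                sep = "\t"),
          paste(sprintf("%.3g", hits$evalue), bits, sep = "\t"))
}

#' Write a hit table as BLAST tabular / 3-column TSV
#'
#' Profile-sequence hits are written in the 12-column BLAST tabular dialect
#' (species-tagged subjects become `species|accession`); profile-profile
#' hits as the 3-column TSV (query, domain family, probability).
#'
#' @param hits a [homology_hits] frame of a single source.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  lines <- if (nrow(hits) == 0) character()
    else if (all(hits$source == "psiblast")) format_blast_tabular(hits)
    else if (all(hits$source == "hhsearch"))
      sprintf("%s\t%s\t%.1f", hits$query, hits$subject, hits$probability)
    else stop("mixed-source hit table")
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic world as a directory of standard-format files
#'
#' Emits `go.obo`, `protein_go.tsv`, `domain_go.tsv` (2-column annotation
#' TSVs), `psiblast.tsv` and `fallback.tsv` (BLAST tabular),
#' `hhsearch.tsv` (3-column TSV), `assignments.tsv` (species, protein,
#' comma-separated domains), `truth.tsv` (2-column target/GO TSV) and
#' `params.tsv` (seed and generation parameters). The same world always
#' produces an identical file tree.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_obo(world$dag, fp("go.obo"))
  write_annotation_tsv(world$protein_annotations, fp("protein_go.tsv"))
  write_annotation_tsv(world$domain_annotations, fp("domain_go.tsv"))
  write_hits(world$psiblast_hits, fp("psiblast.tsv"))
  write_hits(world$fallback_hits, fp("fallback.tsv"))
  write_hits(world$hhsearch_hits, fp("hhsearch.tsv"))
  write_assignments_tsv(world$assignments, fp("assignments.tsv"))
  write_annotation_tsv(world$truth, fp("truth.tsv"))
  flat <- unlist(world$spec)
  params <- data.frame(key = c("seed", names(flat)),
                       value = c(world$seed, unname(flat)))
  utils::write.table(params, fp("params.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
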