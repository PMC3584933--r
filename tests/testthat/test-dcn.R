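path_network <- function() {
  build_dcn(domain_assignments("sp", list(P1 = c("A", "B"),
                                          P2 = c("B", "C"))))
}

test_that("build_dcn draws one edge per co-occurring pair", {
  net <- path_network()
  expect_setequal(igraph::V(net$graph)$name, c("A", "B", "C"))
  el <- igraph::as_edgelist(net$graph)
  expect_equal(nrow(el), 2L)
  key <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key, c("A-B", "B-C"))

  # repeated family in one protein: node, no self-loop
  solo <- build_dcn(domain_assignments("sp", list(P1 = c("A", "A"))))
  expect_equal(igraph::V(solo$graph)$name, "A")
  expect_equal(igraph::ecount(solo$graph), 0L)

  # single-domain proteome is edgeless
  edgeless <- build_dcn(domain_assignments("sp", list(P1 = "A", P2 = "B")))
  expect_equal(igraph::ecount(edgeless$graph), 0L)
})

test_that("build_dcn ignores protein order and duplicates; edges bounded", {
  a1 <- domain_assignments("sp", list(P1 = c("A", "B"), P2 = c("B", "C"),
                                      P3 = c("A", "B")))
  a2 <- domain_assignments("sp", list(P3 = c("B", "A"), P2 = c("C", "B"),
                                      P1 = c("A", "B")))
  g1 <- build_dcn(a1)$graph; g2 <- build_dcn(a2)$graph
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  key <- function(g) apply(igraph::as_edgelist(g), 1,
                           function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key(g1), key(g2))
  for (seed in 1:5) {
    g <- build_dcn(random_graph_world(seed))$graph
    expect_lte(igraph::ecount(g), choose(igraph::vcount(g), 2))
    expect_equal(sum(igraph::which_loop(g)), 0L)
    expect_equal(sum(igraph::which_multiple(g)), 0L)
  }
})

test_that("select_species picks the species of the best hit", {
  hits <- homology_hits(c("T", "T"), c("P68543", "Q1"), "psiblast",
                        evalue = c(3e-95, 1e-3),
                        species = c("hsapiens", "yeast"))
  expect_equal(select_species(hits), "hsapiens")
  expect_equal(select_species(hits[2, ]), "yeast")
  tie <- homology_hits(c("T", "T"), c("S1", "S2"), "psiblast",
                       evalue = c(1e-10, 1e-10),
                       species = c("zebra", "ant"))
  expect_equal(select_species(tie), "ant")
  expect_error(select_species(empty_hits()), "no species")
})

test_that("neighbor_set returns nodes within the radius, centers excluded", {
  net <- path_network()  # A - B - C
  expect_equal(neighbor_set(net, "A", 1), "B")
  expect_setequal(neighbor_set(net, "A", 2), c("B", "C"))
  expect_setequal(neighbor_set(net, c("A", "C"), 1), "B")
  expect_error(neighbor_set(net, "Z", 1), "not in network")

  # multi-center star: union of adjacency sets minus the centers
  star <- build_dcn(domain_assignments("hs", list(
    P1 = c("ubiquitin", "N1"), P2 = c("UBX", "N1", "N2"),
    P3 = c("SEP", "N3"), P4 = c("FERM_N", "N4"), P5 = c("N4", "N5"))))
  centers <- c("ubiquitin", "UBX", "SEP", "FERM_N")
  expect_setequal(neighbor_set(star, centers, 1),
                  c("N1", "N2", "N3", "N4"))
  expect_setequal(neighbor_set(star, centers, 2),
                  c("N1", "N2", "N3", "N4", "N5"))
})

test_that("neighbor_set matches a breadth-first-search oracle", {
  for (seed in 1:30) {
    net <- build_dcn(random_graph_world(seed, n_nodes = 60))
    nodes <- igraph::V(net$graph)$name
    edges <- igraph::as_edgelist(net$graph)
    set.seed(seed + 999)
    centers <- sample(nodes, sample(1:3, 1))
    for (r in 1:2)
      expect_equal(neighbor_set(net, centers, r),
                   oracle_neighbor_set(nodes, edges, centers, r))
  }
})

test_that("neighbor counting scores terms by occurrence frequency", {
  net <- build_dcn(domain_assignments("sp", list(
    P1 = c("center", "N1"), P2 = c("center", "N2"),
    P3 = c("center", "N3"))))
  ann <- annotation_map(list(N1 = "GO:x", N2 = "GO:x", N3 = "GO:y"))
  out <- neighbor_counting_predict(net, "center", ann, target = "T")
  out <- out[order(out$term), ]
  expect_equal(out$term, c("GO:x", "GO:y"))
  expect_equal(out$confidence, c(0.3 * 2 / 3, 0.3 * 1 / 3))
  expect_equal(unique(out$level), 3L)

  # one GO term over all neighbors attains the 0.3 upper bound
  one <- neighbor_counting_predict(
    net, "center", annotation_map(list(N1 = "GO:z")), target = "T")
  expect_equal(one$confidence, 0.3)
})

test_that("radius-2 fallback fires only when radius-1 is unannotated", {
  # center - mid - far; only far annotated
  net <- build_dcn(domain_assignments("sp", list(
    P1 = c("center", "mid"), P2 = c("mid", "far"))))
  ann <- annotation_map(list(far = "GO:z"))
  out <- neighbor_counting_predict(net, "center", ann)
  expect_equal(out$term, "GO:z")
  expect_equal(out$confidence, 0.3)

  # once mid is annotated, far (distance 2) is not consulted
  ann2 <- annotation_map(list(mid = "GO:m", far = "GO:z"))
  out2 <- neighbor_counting_predict(net, "center", ann2)
  expect_equal(out2$term, "GO:m")

  # nothing annotated at either radius
  expect_equal(nrow(neighbor_counting_predict(
    net, "center", annotation_map(list()))), 0L)
})

test_that("neighbor-counting confidences always sum to 0.3", {
  terms <- sprintf("GO:%07d", 1:8)
  for (seed in 1:25) {
    net <- build_dcn(random_graph_world(seed, n_nodes = 20))
    nodes <- igraph::V(net$graph)$name
    set.seed(seed)
    ann <- lapply(stats::setNames(nm = nodes), function(d)
      if (runif(1) < 0.5) sample(terms, sample(1:3, 1)) else character())
    centers <- sample(nodes, 2)
    out <- neighbor_counting_predict(net, centers, annotation_map(ann))
    if (nrow(out) > 0) {
      expect_equal(sum(out$confidence), 0.3)
      expect_true(all(out$confidence > 0 & out$confidence <= 0.3))
    }
    # removing an unannotated neighbor leaves the GO term set unchanged
    unann <- setdiff(neighbor_set(net, centers, 1),
                     names(ann)[lengths(ann) > 0])
    if (length(unann) > 0 && nrow(out) > 0) {
      ann2 <- ann[setdiff(names(ann), unann[[1]])]
      net2 <- net
      net2$graph <- igraph::delete_vertices(net$graph, unann[[1]])
      out2 <- neighbor_counting_predict(net2, centers,
                                        annotation_map(ann2))
      expect_setequal(out2$term, out$term)
    }
  }
})

test_that("assignment tables and networks round-trip through files", {
  asn <- list(sp1 = domain_assignments("sp1", list(P1 = c("A", "B"),
                                                   P2 = character())),
              sp2 = domain_assignments("sp2", list(Q1 = c("B", "C", "B"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments_tsv(asn, path)
  back <- read_assignments_tsv(path)
  expect_setequal(names(back), c("sp1", "sp2"))
  expect_equal(back$sp1$proteins$P1, c("A", "B"))
  expect_length(back$sp1$proteins$P2, 0)
  expect_equal(back$sp2$proteins$Q1, c("B", "C", "B"))

  net <- path_network()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dcn_tsv(net, tsv)
  expect_equal(length(readLines(tsv)), 2L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_dcn_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2L)
})
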