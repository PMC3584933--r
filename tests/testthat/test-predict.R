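test_that("finalize merges duplicates, sorts, caps and clips", {
  dup <- prediction_frame("T", c("GO:x", "GO:x"), c(0.9, 0.5), c(1L, 2L))
  out <- finalize(dup)
  expect_equal(out$term, "GO:x")
  expect_equal(out$confidence, 0.9)

  many <- prediction_frame("T", sprintf("GO:%07d", 1:150),
                           rep(c(0.9, 0.5, 0.2), 50), 1L)
  capped <- finalize(many, 100)
  expect_equal(nrow(capped), 100L)
  dropped <- setdiff(many$term, capped$term)
  expect_true(min(capped$confidence) >=
              max(many$confidence[many$term %in% dropped]))
  # descending confidence, GO id breaks ties
  expect_true(all(diff(capped$confidence) <= 0))
  grp <- capped[capped$confidence == 0.9, "term"]
  expect_equal(grp, sort(grp))

  hot <- prediction_frame("T", "GO:x", 1.2, 1L)
  expect_equal(finalize(hot)$confidence, 1.0)
})

test_that("predictor 1 keeps each level in its score interval", {
  ann <- annotation_map(list(S1 = c("GO:a", "GO:b")))
  dom_ann <- annotation_map(list(D1 = "GO:c"))
  psi <- homology_hits("T", "S1", "psiblast", evalue = 1e-40)
  hh <- homology_hits("T", "D1", "hhsearch", probability = 92)

  strong <- predictor1("T", psiblast_hits = psi, annotations = ann)
  expect_true(all(strong$confidence >= 0.6 & strong$confidence <= 1))
  expect_true(all(strong$level == 1L))

  dom_only <- predictor1("T", hhsearch_hits = hh,
                         domain_annotations = dom_ann)
  expect_true(all(dom_only$confidence >= 0.54 & dom_only$confidence <= 0.6))
  expect_true(all(dom_only$level == 2L))

  both <- predictor1("T", psiblast_hits = psi, hhsearch_hits = hh,
                     annotations = ann, domain_annotations = dom_ann)
  l1 <- both$confidence[both$level == 1L]
  l2 <- both$confidence[both$level == 2L]
  expect_true(min(l1) >= max(l2))  # nested intervals
})

test_that("hard cases fall back to weak hits and the species network", {
  # no hit passes either cutoff -> hard case
  weak <- homology_hits("T", "W1", "psiblast", evalue = 2, species = "hs")
  hh <- homology_hits("T", "center", "hhsearch", probability = 55)
  ann <- annotation_map(list(W1 = "GO:w"))
  dom_ann <- annotation_map(list(N1 = "GO:n"))
  net <- build_dcn(domain_assignments("hs", list(P1 = c("center", "N1"))))

  out <- suppressMessages(predictor1(
    "T", fallback_hits = weak, hhsearch_hits = hh, annotations = ann,
    domain_annotations = dom_ann, networks = list(hs = net),
    species_hits = weak))
  # fallback hit scored by the unfloored formula, below genuine level 1
  expect_equal(out$confidence[out$term == "GO:w"],
               score_psiblast(2, floor = FALSE))
  expect_lt(out$confidence[out$term == "GO:w"], 0.6)
  # network prediction present in (0, 0.3]
  expect_equal(out$confidence[out$term == "GO:n"], 0.3)
  expect_equal(out$level[out$term == "GO:n"], 3L)

  none <- suppressMessages(predictor1("T"))
  expect_equal(nrow(none), 0L)
})

test_that("domains missing from the species network are dropped", {
  weak <- homology_hits("T", "W1", "psiblast", evalue = 2, species = "hs")
  hh <- homology_hits(c("T", "T"), c("center", "ghost"), "hhsearch",
                      probability = c(55, 60))
  dom_ann <- annotation_map(list(N1 = "GO:n"))
  net <- build_dcn(domain_assignments("hs", list(P1 = c("center", "N1"))))
  expect_message(
    out <- predictor1("T", fallback_hits = weak, hhsearch_hits = hh,
                      domain_annotations = dom_ann,
                      networks = list(hs = net), species_hits = weak),
    "ghost")
  expect_equal(out$term, "GO:n")
})

test_that("predictor 2 normalizes the weighted GO-term frequency", {
  # one source each for GO:g -> W = 4 + 2 + 1 = 7, the maximum
  ann <- annotation_map(list(S1 = "GO:g"))
  dom_ann <- annotation_map(list(D1 = "GO:g", N1 = c("GO:g", "GO:h")))
  psi <- homology_hits("T", "S1", "psiblast", evalue = 1e-10,
                       species = "hs")
  hh <- homology_hits("T", "D1", "hhsearch", probability = 95)
  net <- build_dcn(domain_assignments("hs", list(P1 = c("D1", "N1"))))

  out <- predictor2("T", psiblast_hits = psi, hhsearch_hits = hh,
                    annotations = ann, domain_annotations = dom_ann,
                    networks = list(hs = net), species_hits = psi)
  expect_equal(out$confidence[out$term == "GO:g"], 1.0)   # W = 7
  expect_equal(out$confidence[out$term == "GO:h"], 1 / 7) # DCN only
  expect_equal(max(out$confidence), 1.0)

  # single psiblast source: top term still exactly 1
  solo <- predictor2("T", psiblast_hits = psi, annotations = ann)
  expect_equal(solo$confidence, 1.0)

  empty <- suppressMessages(predictor2("T"))
  expect_equal(nrow(empty), 0L)
})

test_that("predictor 2 counts every passing profile-sequence hit", {
  ann <- annotation_map(list(S1 = "GO:g", S2 = "GO:g", S3 = "GO:h"))
  psi <- homology_hits(rep("T", 3), c("S1", "S2", "S3"), "psiblast",
                       evalue = c(1e-10, 1e-5, 1e-3))
  out <- predictor2("T", psiblast_hits = psi, annotations = ann)
  expect_equal(out$confidence[out$term == "GO:g"], 1.0)  # W = 8
  expect_equal(out$confidence[out$term == "GO:h"], 0.5)  # W = 4
})

test_that("predictor 3 scores terms by hit frequency", {
  ann <- annotation_map(list(S1 = "GO:g", S2 = c("GO:g", "GO:h"),
                             S3 = "GO:g", S4 = "GO:g", S5 = character()))
  hits <- homology_hits(rep("T", 5), paste0("S", 1:5), "psiblast",
                        evalue = c(0.5, 2, 5, 9, 1))
  out <- predictor3("T", hits, ann)
  # S5 is unannotated: 4 annotated hits in the denominator
  expect_equal(out$confidence[out$term == "GO:g"], 1.0)
  expect_equal(out$confidence[out$term == "GO:h"], 0.25)
  expect_equal(nrow(predictor3("T", empty_hits(), ann)), 0L)
  # 3 of 4 annotated hits
  ann2 <- annotation_map(list(S1 = "GO:g", S2 = "GO:g", S3 = "GO:g",
                              S4 = "GO:h"))
  out2 <- predictor3("T", hits[1:4, ], ann2)
  expect_equal(out2$confidence[out2$term == "GO:g"], 0.75)
})

test_that("predictors are deterministic functions of their inputs", {
  w <- make_world(world_spec(n_targets = 6), seed = 3)
  run <- function() suppressMessages(predict_targets(
    w$targets, 1, psiblast_hits = w$psiblast_hits,
    hhsearch_hits = w$hhsearch_hits, fallback_hits = w$fallback_hits,
    annotations = w$protein_annotations,
    domain_annotations = w$domain_annotations, networks = w$networks))
  expect_identical(run(), run())
})

test_that("CAFA output format: two decimals, 0.01 floor, sorted", {
  preds <- prediction_frame(c("T2", "T1", "T1"),
                            c("GO:0000001", "GO:0000002", "GO:0000001"),
                            c(1.0, 0.004, 0.5), 0L)
  path <- withr::local_tempfile()
  write_cafa(preds, path)
  lines <- readLines(path)
  expect_equal(lines, c("T1\tGO:0000001\t0.50",
                        "T1\tGO:0000002\t0.01",
                        "T2\tGO:0000001\t1.00"))
  back <- read_cafa(path)
  expect_equal(back$confidence, c(0.5, 0.01, 1.0))

  dup <- prediction_frame(c("T1", "T1"), c("GO:x", "GO:x"), c(0.9, 0.8), 0L)
  expect_error(write_cafa(dup, path), "finalized")

  path2 <- withr::local_tempfile()
  write_cafa(empty_predictions(), path2)
  expect_length(readLines(path2), 0L)
})
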