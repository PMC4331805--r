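test_that("hypergeometric tail matches exact rational values on small cases", {
  # frozen from exact integer summation of the tail definition
  expect_equal(hypergeom_pvalue(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(12, 5, 6, 3), 1 / 2, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(100, 5, 5, 5), 1 / 75287520, tolerance = 1e-12)
  expect_identical(hypergeom_pvalue(100, 30, 10, 0), 1)
  expect_identical(hypergeom_pvalue(5000, 200, 50, 0), 1)
})

test_that("hypergeometric invariants: monotone in m, symmetric in (M, n)", {
  for (m in 1:9) {
    expect_lt(hypergeom_pvalue(60, 20, 10, m),
              hypergeom_pvalue(60, 20, 10, m - 1))
  }
  set.seed(5)
  for (i in 1:20) {
    N <- sample(20:500, 1L)
    M <- sample.int(N, 1L); n <- sample.int(N, 1L)
    m <- sample.int(min(n, M), 1L)
    expect_equal(hypergeom_pvalue(N, M, n, m), hypergeom_pvalue(N, n, M, m),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric invariant violations name the broken inequality", {
  expect_error(hypergeom_pvalue(10, 11, 3, 2), "M <= N")
  expect_error(hypergeom_pvalue(10, 4, 11, 2), "n <= N")
  expect_error(hypergeom_pvalue(10, 4, 3, 4), "m <= min\\(n, M\\)")
})

test_that("log-space tail agrees with the exact integer oracle on random instances", {
  tri <- build_big_binom(60L)
  set.seed(17)
  for (i in 1:40) {
    N <- sample(3:60, 1L)
    M <- sample.int(N, 1L)
    n <- sample.int(N, 1L)
    got <- exp(lncfun:::hypergeom_logp_tails(N, M, n))
    want <- oracle_hyper_tails(N, M, n, tri)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("extreme tails are computed without underflow and cross-check phyper", {
  # independent route: R's own hypergeometric distribution function
  cases <- list(c(20447, 1581, 458, 208), c(20447, 3253, 74, 38),
                c(20000, 100, 500, 90), c(5000, 2500, 2000, 1500))
  for (cs in cases) {
    mine <- hypergeom_pvalue(cs[1], cs[2], cs[3], cs[4], log.p = TRUE)
    ref <- phyper(cs[4] - 1, cs[2], cs[1] - cs[2], cs[3],
                  lower.tail = FALSE, log.p = TRUE)
    expect_equal(mine, ref, tolerance = 1e-8)
  }
  expect_gt(hypergeom_pvalue(20447, 1581, 458, 208), 0)  # no flush to zero
})

test_that("BH and BY match hand-stepped computations exactly", {
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(rep(0.03, 5)), rep(0.03, 5))
  # step-up by hand on 3 values: (0.01*3/1, 0.02*3/2, 0.05*3/3) with
  # cumulative min from the largest rank -> (0.03, 0.03, 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.05)), c(0.03, 0.03, 0.05))
  expect_equal(benjamini_hochberg(c(0.05, 0.01, 0.02)), c(0.05, 0.03, 0.03))
  # BY adds the harmonic factor c(2) = 1.5: (0.002, 0.01) -> (0.003, 0.015)
  expect_equal(benjamini_yekutieli(c(0.001, 0.01)), c(0.003, 0.015))
  expect_equal(benjamini_yekutieli(0.2), 0.2)  # c(1) = 1
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "in \\[0, 1\\]")
  expect_error(benjamini_yekutieli(c(-0.1)), "in \\[0, 1\\]")
})

test_that("BY >= BH >= raw elementwise, capped at 1, order-preserving", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(2:60, 1L))
    bh <- benjamini_hochberg(p)
    by <- benjamini_yekutieli(p)
    expect_true(all(bh >= p - 1e-15))
    expect_true(all(by >= bh - 1e-15))
    expect_true(all(by <= 1))
    o <- order(p)
    expect_true(all(diff(bh[o]) >= -1e-15))
    expect_equal(bh, oracle_bh(p))
    expect_equal(by, oracle_by(p))
  }
})

test_that("enrich tests only terms passing the size filter and returns all of them", {
  mt <- micro_terms()
  res <- suppressMessages(
    enrich(sprintf("G%02d", 3:8), mt$ann, mt$universe, correction = "BY"))
  expect_false("T:A" %in% res$term_id)  # M = 4 < 5, never tested
  expect_identical(res$term_id, "T:B")
  expect_identical(res$m, 6L)
  expect_identical(res$N, 40L)
  # perfect overlap: p is the exact probability of drawing the whole term
  expect_equal(res$p_raw, hypergeom_pvalue(40, 6, 6, 6))
  expect_true(res$significant)
})

test_that("single fully-annotated term is recovered at the exact tail probability", {
  genes <- sprintf("G%03d", 1:100)
  dag <- structure(
    list(terms = data.frame(id = "T:X", name = "t", namespace = "biological_process"),
         edges = data.frame(child = character(0), parent = character(0),
                            type = character(0)),
         obsolete = character(0)), class = "ontology_dag")
  ann <- propagate_annotations(annotation_set(list("T:X" = genes[1:5]), dag))
  res <- suppressMessages(enrich(genes[1:5], ann, genes))
  expect_equal(res$p_raw, 1 / choose(100, 5), tolerance = 1e-12)
  expect_true(res$significant)
})

test_that("enrich drops out-of-universe queries and rejects empty ones", {
  mt <- micro_terms()
  expect_warning(
    res <- suppressMessages(enrich(c("G03", "NOPE"), mt$ann, mt$universe)),
    "outside the universe")
  expect_identical(res$n[1], 1L)
  expect_error(suppressWarnings(suppressMessages(enrich("NOPE", mt$ann, mt$universe))),
               "empty query")
  expect_error(enrich("G03", mt$ann, character(0)), "empty universe")
})

test_that("zero-overlap queries are never significant", {
  mt <- micro_terms()
  res <- suppressMessages(enrich(sprintf("G%02d", 30:40), mt$ann, mt$universe))
  expect_identical(res$m, 0L)
  expect_identical(res$p_raw, 1)
  expect_false(any(res$significant))
})

test_that("enrichment is deterministic: identical calls give identical output", {
  fx <- generate_fixture(fixture_config(seed = 2, n_modules = 3,
                                        n_background_coding = 40,
                                        n_background_lnc = 4))
  ann <- propagate_annotations(fx$annotations)
  universe <- names(fx$catalog)[fx$catalog == "protein_coding"]
  q <- fx$truth[[2]]$coding_ids
  r1 <- suppressMessages(enrich(q, ann, universe, correction = "BY"))
  r2 <- suppressMessages(enrich(q, ann, universe, correction = "BY"))
  expect_identical(r1, r2)
  path1 <- tempfile(); path2 <- tempfile()
  write_enrichment_tsv(r1, path1); write_enrichment_tsv(r2, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("annotate_lncrna applies the co-expression size filter", {
  fx <- generate_fixture(fixture_config(seed = 4))
  parts <- suppressMessages(split_by_biotype(fx$expression, fx$catalog))
  net <- suppressMessages(build_network(parts$lnc, parts$coding))
  ann <- propagate_annotations(fx$annotations)
  universe <- sort(rownames(parts$coding))

  res <- suppressMessages(annotate_lncrna(fx$truth[[1]]$lncrna_ids[1], net,
                                          ann, fx$pathways, universe))
  expect_identical(res$status, "annotated")
  expect_identical(attr(res$go, "correction_method"), "BY")
  expect_identical(attr(res$pathway, "correction_method"), "BH")
  expect_true(fx$truth[[1]]$go_term %in% res$go$term_id[res$go$significant])

  unknown <- suppressMessages(annotate_lncrna("NOT_A_GENE", net, ann,
                                              fx$pathways, universe))
  expect_identical(unknown$status, "not_annotatable")
  expect_match(unknown$reason, "absent from network")
})

test_that("null queries reject at roughly the nominal raw rate", {
  # co-expressed sets drawn uniformly from the universe: the raw enrichment
  # p-values should be near-uniform (sub-uniform from discreteness)
  fx <- generate_fixture(fixture_config(seed = 12, n_modules = 4,
                                        coding_per_module = 25,
                                        n_background_coding = 150))
  ann <- propagate_annotations(fx$annotations)
  universe <- names(fx$catalog)[fx$catalog == "protein_coding"]
  set.seed(20)
  praws <- replicate(60, {
    q <- sample(universe, 40)
    suppressMessages(enrich(q, ann, universe))$p_raw
  })
  frac <- mean(unlist(praws) < 0.05)
  expect_lt(frac, 0.08)
})
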