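test_that("pearson_r matches the definition on exact and hand-computed cases", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(8, 6, 4, 2)), -1)
  # cov((1,2,3),(1,3,2)) / (sd * sd) = (1/2) / 1 = 1/2, by rational arithmetic
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r is symmetric and invariant to positive affine maps", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(8)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    expect_equal(pearson_r(a * x + b, y), pearson_r(x, y), tolerance = 1e-12)
    expect_gte(pearson_r(x, y), -1)
    expect_lte(pearson_r(x, y), 1)
  }
})

test_that("pearson_pvalue matches an independent t-tail integration oracle", {
  expect_equal(pearson_pvalue(0, 19), 1)
  expect_equal(pearson_pvalue(1, 19), 0)
  expect_equal(pearson_pvalue(-1, 5), 0)
  # two-sided p at r = 0.9, n = 19: twice the upper t(17) tail at
  # t = 0.9 * sqrt(17) / sqrt(0.19), via numerical integration of the density
  tstat <- 0.9 * sqrt(17) / sqrt(1 - 0.81)
  dens <- function(u, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, tstat, Inf, df = 17, rel.tol = 1e-12)$value
  expect_equal(pearson_pvalue(0.9, 19), 2 * tail, tolerance = 1e-9)
  expect_error(pearson_pvalue(0.5, 2), "n >= 3")
})

test_that("pearson_pvalue decreases in |r| and in n", {
  rs <- seq(0.05, 0.95, by = 0.05)
  p_by_r <- pearson_pvalue(rs, 19)
  expect_true(all(diff(p_by_r) < 0))
  p_by_n <- vapply(c(5, 10, 19, 50), function(n) pearson_pvalue(0.5, n),
                   numeric(1L))
  expect_true(all(diff(p_by_n) < 0))
})

test_that("all-pairs correlation enumerates the full cross product", {
  mat <- micro_expression()
  parts <- suppressMessages(split_by_biotype(mat, micro_catalog()))
  pairs <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding))
  expect_identical(nrow(pairs), 2L * 4L)
  expect_identical(attr(pairs, "n_conditions"), 10L)
  # lexicographic order by lncRNA then coding gene
  expect_identical(pairs$lncrna_id, rep(c("L1", "L2"), each = 4L))
  expect_identical(pairs$coding_id, rep(c("C1", "C2", "C3", "C4"), 2L))
  # exact linear dependence gives r = +/-1
  expect_equal(pairs$r[pairs$lncrna_id == "L1" & pairs$coding_id == "C1"], 1)
  expect_equal(pairs$r[pairs$lncrna_id == "L1" & pairs$coding_id == "C3"], -1)
  expect_equal(pairs$r[pairs$lncrna_id == "L2" & pairs$coding_id == "C3"], 1)
})

test_that("zero-variance genes are dropped, not assigned r = 0", {
  mat <- micro_expression()
  mat <- rbind(mat, C5 = rep(2, 10))
  cat_ <- c(micro_catalog(), C5 = "protein_coding")
  parts <- suppressMessages(split_by_biotype(mat, cat_))
  pairs <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding))
  expect_false("C5" %in% pairs$coding_id)
  expect_identical(nrow(pairs), 2L * 4L)
})

test_that("condition mismatch is a hard error", {
  mat <- micro_expression()
  parts <- suppressMessages(split_by_biotype(mat, micro_catalog()))
  swapped <- parts$coding[, rev(colnames(parts$coding))]
  expect_error(coexpress_all_pairs(parts$lnc, swapped), "same conditions")
})

test_that("adjust_and_filter applies BH over the whole family with strict cutoffs", {
  mat <- micro_expression()
  parts <- suppressMessages(split_by_biotype(mat, micro_catalog()))
  pairs <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding))
  net <- suppressMessages(adjust_and_filter(pairs))
  expect_s3_class(net, "coexpression_network")
  # every retained edge satisfies the rule it was built with
  expect_true(all(abs(net$edges$r) > 0.9))
  expect_true(all(net$edges$p_adj < 0.05))
  expect_true(all(net$edges$p_adj >= net$edges$p_raw))
  # edges are a subset of input pairs and unique
  expect_false(anyDuplicated(net$edges[c("lncrna_id", "coding_id")]) > 0)
  # BH adjustment over the family matches the hand-stepped oracle
  expect_equal(net$edges$p_adj,
               oracle_bh(pairs$p_raw)[match(
                 paste(net$edges$lncrna_id, net$edges$coding_id),
                 paste(pairs$lncrna_id, pairs$coding_id))])
})

test_that("filtering is anti-monotone in r_cutoff and alpha", {
  fx <- generate_fixture(fixture_config(seed = 11, n_modules = 2,
                                        coding_per_module = 8,
                                        n_background_coding = 30,
                                        n_background_lnc = 5, rho = 0.8))
  parts <- suppressMessages(split_by_biotype(fx$expression, fx$catalog))
  pairs <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding))
  key <- function(net) paste(net$edges$lncrna_id, net$edges$coding_id)
  loose <- suppressMessages(adjust_and_filter(pairs, r_cutoff = 0.5, alpha = 0.1))
  tight_r <- suppressMessages(adjust_and_filter(pairs, r_cutoff = 0.8, alpha = 0.1))
  tight_a <- suppressMessages(adjust_and_filter(pairs, r_cutoff = 0.5, alpha = 0.01))
  expect_true(all(key(tight_r) %in% key(loose)))
  expect_true(all(key(tight_a) %in% key(loose)))
})

test_that("blocked computation is invariant to block size", {
  fx <- generate_fixture(fixture_config(seed = 3, n_modules = 2,
                                        coding_per_module = 6,
                                        n_background_coding = 20,
                                        n_background_lnc = 4))
  parts <- suppressMessages(split_by_biotype(fx$expression, fx$catalog))
  p1 <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding, block_size = 1L))
  p2 <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding, block_size = 7L))
  p3 <- suppressMessages(coexpress_all_pairs(parts$lnc, parts$coding, block_size = 512L))
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("coexpressed_set returns unique neighbours and warns on unknown IDs", {
  mat <- micro_expression()
  parts <- suppressMessages(split_by_biotype(mat, micro_catalog()))
  net <- suppressMessages(build_network(parts$lnc, parts$coding))
  s1 <- coexpressed_set(net, "L1")
  expect_true(all(c("C1", "C2") %in% s1))
  expect_false(anyDuplicated(s1) > 0)
  expect_warning(s0 <- coexpressed_set(net, "NOPE"), "absent")
  expect_identical(s0, character(0))
})

test_that("network TSV round-trips edges and parameters", {
  mat <- micro_expression()
  parts <- suppressMessages(split_by_biotype(mat, micro_catalog()))
  net <- suppressMessages(build_network(parts$lnc, parts$coding))
  path <- tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path)
  expect_equal(back$edges, net$edges)
  expect_identical(back$n_conditions, net$n_conditions)
  expect_identical(back$n_tested, net$n_tested)
  expect_identical(back$method, net$method)
})
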