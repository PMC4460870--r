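# 10-row hand-built fixture exercising every filter rule
fixture_expression <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:10),
    mrna_level = c(0.4, 0.5, 0.6, 2, 5, 10, 1, 3, 0.2, 8),
    protein_abundance = c(10, 20, 30, 100, 0, 50, 25, 60, 5, 80),
    fp_rep1 = c(2.0, 1.0, 3.0, 2.0, 0.9, 4.0, 2.0, 1.5, 2.2, 3.0),
    fp_rep2 = c(2.8, 1.6, 3.0, 2.9, 0.9, 4.4, 2.0, 1.5, 2.2, 4.6),
    mr_rep1 = c(1.2, 2.0, 2.0, 1.4, 2.0, 0.8, 1.1, 2.0, 3.0, 2.0),
    mr_rep2 = c(1.3, 2.0, 2.1, 1.4, 2.0, 0.9, 1.2, 2.0, 3.0, 2.1))
}

test_that("TE and RD are plain ratios with missing on zero denominators", {
  expect_equal(translation_efficiency(100, 4), 25.0)
  expect_equal(translation_efficiency(0, 4), 0.0)
  expect_true(is.na(translation_efficiency(100, 0)))
  expect_equal(ribosome_density(30, 10), 3.0)
  expect_equal(ribosome_density(mean(c(2, 4)), mean(c(1, 1))), 3.0)
  expect_true(is.na(ribosome_density(5, 0)))
})

test_that("mRNA-level filter is strictly greater than 0.5 molecules/cell", {
  rec <- tibble::tibble(gene_id = c("a", "b", "c"),
                        mrna_level = c(0.4, 0.5, 0.6))
  kept <- filter_mrna_level(rec)
  expect_identical(kept$gene_id, "c")
  all_above <- tibble::tibble(gene_id = "x", mrna_level = 2)
  expect_identical(filter_mrna_level(all_above), all_above)
  expect_identical(nrow(filter_mrna_level(rec[0, ])), 0L)
})

test_that("RPKM filter applies mean > 1 and max/min < 1.5 to both series", {
  # (1.0, 1.6): mean 1.3 > 1 but ratio 1.6 >= 1.5 -> dropped
  r1 <- tibble::tibble(gene_id = "a", fp_rep1 = 1.0, fp_rep2 = 1.6,
                       mr_rep1 = 2.0, mr_rep2 = 2.0)
  expect_identical(nrow(filter_rpkm(r1)), 0L)
  # (2.0, 2.8): mean 2.4, ratio 1.4 -> kept
  r2 <- tibble::tibble(gene_id = "b", fp_rep1 = 2.0, fp_rep2 = 2.8,
                       mr_rep1 = 2.0, mr_rep2 = 2.0)
  expect_identical(nrow(filter_rpkm(r2)), 1L)
  # single replicate: variation vacuously consistent
  r3 <- tibble::tibble(gene_id = "c", fp_rep1 = 1.5, mr_rep1 = 1.5)
  expect_identical(nrow(filter_rpkm(r3)), 1L)
  # the mRNA series must pass too
  r4 <- tibble::tibble(gene_id = "d", fp_rep1 = 2.0, fp_rep2 = 2.0,
                       mr_rep1 = 0.5, mr_rep2 = 0.6)
  expect_identical(nrow(filter_rpkm(r4)), 0L)
})

test_that("filters match hand application on the 10-row fixture and are idempotent", {
  fx <- fixture_expression()
  # hand: mRNA > 0.5 keeps g3,g4,g5,g6,g7,g8,g10 (7 rows)
  f1 <- filter_mrna_level(fx)
  expect_identical(f1$gene_id, paste0("g", c(3, 4, 5, 6, 7, 8, 10)))
  # hand RPKM rules per gene:
  # g1 fp 2.0/2.8 ratio 1.4 mean 2.4 ok; mr 1.2/1.3 ratio ~1.083 mean 1.25 ok -> keep
  # g2 fp ratio 1.6 -> drop ; g3 ok ; g4 fp ratio 1.45 ok -> keep
  # g5 fp mean 0.9 -> drop ; g6 mr mean 0.85 -> drop ; g7 ok ; g8 ok
  # g9 ok (fp 2.2/2.2, mr 3.0/3.0) ; g10 fp ratio 1.533 -> drop
  f2 <- filter_rpkm(fx)
  expect_identical(f2$gene_id, paste0("g", c(1, 3, 4, 7, 8, 9)))
  expect_identical(filter_mrna_level(f1), f1)
  expect_identical(filter_rpkm(f2), f2)
})

test_that("gene_metrics flags filters without dropping rows", {
  fx <- fixture_expression()
  gm <- gene_metrics(fx)
  expect_identical(nrow(gm), nrow(fx))
  expect_identical(gm$gene_id[gm$passed_te_filter],
                   paste0("g", c(3, 4, 5, 6, 7, 8, 10)))
  expect_identical(gm$gene_id[gm$passed_rd_filter],
                   paste0("g", c(1, 3, 4, 7, 8, 9)))
  expect_equal(gm$te[4], 100 / 2)
  expect_equal(gm$rd[3], 3.0 / 2.05)
})

test_that("TE/RD recomputed from a noise-free synthetic table equal the planted truths", {
  spec <- toy_model_spec(yields = c(A = 2, B = 1, C = 0.7))
  m <- build_toy_model(spec)
  prot <- gen_proteome(40, spec, seed = 9, length = 120)
  sup <- supply_table(m, toy_aa_map(m), prot)
  params <- planted_params(n_genes = 40L, seed = 3, replicate_cv = 0)
  expr <- gen_expression(sup$supply, params)
  gm <- gene_metrics(expr)
  expect_equal(gm$te, expr$te_true, tolerance = 1e-12)
  expect_equal(gm$rd, expr$rd_true, tolerance = 1e-12)
  expect_true(all(gm$passed_rd_filter == (expr$fp_rep1 > 1 & expr$mr_rep1 > 1)))
})

test_that("build_gene_table inner-joins and rejects malformed id spaces", {
  sup <- tibble::tibble(protein_id = c("g1", "g2", "g3"),
                        supply = c(3, 2, 1), mu = 1, beta = 0.3,
                        status = "optimal")
  met <- tibble::tibble(gene_id = c("g2", "g3"), te = c(1, 2), rd = c(2, 1))
  gt <- build_gene_table(sup, met)
  expect_identical(nrow(gt), 2L)
  expect_setequal(gt$gene_id, c("g2", "g3"))
  dup <- tibble::tibble(gene_id = c("g2", "g2"), te = 1:2, rd = 1:2)
  expect_error(build_gene_table(sup, dup), "g2")
  disjoint <- tibble::tibble(gene_id = c("x1", "x2"), te = 1:2, rd = 1:2)
  expect_error(build_gene_table(sup, disjoint), "no shared ids")
  # id mapping between protein and gene spaces
  idm <- data.frame(protein_id = c("g1", "g2"), gene_id = c("y1", "y2"))
  met2 <- tibble::tibble(gene_id = c("y1", "y2"), te = c(1, 2), rd = c(2, 1))
  gt2 <- build_gene_table(sup, met2, id_map = idm)
  expect_setequal(gt2$gene_id, c("y1", "y2"))
})
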