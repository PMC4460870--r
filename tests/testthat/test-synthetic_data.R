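test_that("toy model construction gives hand-computable optima and scales linearly", {
  m <- toy1_model()
  expect_equal(max_growth(m), 20 / 3, tolerance = 1e-9)
  mu <- max_growth(m)
  expect_equal(amino_acid_supply(m, toy_aa_map(m), c(A = 1), beta = 0.3,
                                 mu = mu)$supply, 14, tolerance = 1e-6)
  # doubling all yields doubles growth and supplies (LP scaling)
  spec2 <- toy_model_spec(yields = c(A = 4, B = 2), substrate_uptake = 10)
  m2 <- build_toy_model(spec2)
  mu2 <- max_growth(m2)
  expect_equal(mu2, 2 * mu, tolerance = 1e-8)
  expect_equal(amino_acid_supply(m2, toy_aa_map(m2), c(A = 1), beta = 0.3,
                                 mu = mu2)$supply, 28, tolerance = 1e-5)
})

test_that("gen_proteome is seed-deterministic with the stated boundary behaviour", {
  spec <- toy_model_spec(yields = c(A = 2, B = 1, C = 0.8))
  p1 <- gen_proteome(20, spec, seed = 5, length = 90)
  p2 <- gen_proteome(20, spec, seed = 5, length = 90)
  expect_identical(vapply(p1, `[[`, character(1), "sequence"),
                   vapply(p2, `[[`, character(1), "sequence"))
  p3 <- gen_proteome(20, spec, seed = 6, length = 90)
  expect_false(identical(vapply(p1, `[[`, character(1), "sequence"),
                         vapply(p3, `[[`, character(1), "sequence")))
  # bias 1: every sequence is 100% the cheapest residue (A has top yield)
  pb <- gen_proteome(5, spec, composition_bias = 1, seed = 1, length = 30)
  for (p in pb) expect_identical(p$sequence, strrep("A", 30))
  # bias 0: mean composition uniform within 3 SE of the generator's spread
  pu <- gen_proteome(500, spec, composition_bias = 0, seed = 2, length = 300)
  freqA <- vapply(pu, function(p) {
    f <- p$aa_freq; if ("A" %in% names(f)) f[["A"]] else 0
  }, numeric(1))
  se <- stats::sd(freqA) / sqrt(length(freqA))
  expect_lt(abs(mean(freqA) - 1 / 3), 3 * se)
})

test_that("the copula plants the target Spearman correlation", {
  withr::with_seed(77, supplies <- rlnorm(2000))
  params <- planted_params(target_spearman_supply_te = 0.30,
                           n_genes = 2000L, seed = 101)
  expr <- gen_expression(supplies, params)
  r <- spearman(expr$supply, expr$te_true)$r
  expect_lt(abs(r - 0.30), 0.05)
  # target 0: independence
  params0 <- planted_params(target_spearman_supply_te = 0,
                            n_genes = 2000L, seed = 102)
  expr0 <- gen_expression(supplies, params0)
  expect_lt(abs(spearman(expr0$supply, expr0$te_true)$r), 0.05)
  # determinism
  expr_b <- gen_expression(supplies, params)
  expect_identical(expr, expr_b)
})

test_that("zero replicate noise makes replicates identical and filters transparent", {
  withr::with_seed(55, supplies <- rlnorm(400))
  params <- planted_params(n_genes = 400L, seed = 7, replicate_cv = 0)
  expr <- gen_expression(supplies, params)
  expect_identical(expr$fp_rep1, expr$fp_rep2)
  expect_identical(expr$mr_rep1, expr$mr_rep2)
  kept <- filter_rpkm(expr)
  expect_identical(kept$gene_id,
                   expr$gene_id[expr$fp_rep1 > 1 & expr$mr_rep1 > 1])
})

test_that("gen_starvation plants the buffering profile and is deterministic", {
  withr::with_seed(66, {
    rec <- tibble::tibble(gene_id = seq_len(500), supply = runif(500),
                          rd = rlnorm(500), mrna_level = rlnorm(500, 3))
  })
  params <- planted_params(n_genes = 500L, seed = 12, buffering_delta = 0.2)
  sv1 <- gen_starvation(rec, params)
  sv2 <- gen_starvation(rec, params)
  expect_identical(sv1, sv2)
  expect_equal(sv1$fold_change, sv1$rd_starved / sv1$rd_normal)
  # median fold change of PAAS exceeds WAAS in nearly all seeded replicates
  hits <- vapply(1:40, function(s) {
    sv <- gen_starvation(rec, planted_params(n_genes = 500L, seed = s,
                                             buffering_delta = 0.2))
    sp <- split_waas_paas(sv)
    stats::median(sp$paas$fold_change) > stats::median(sp$waas$fold_change)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("end-to-end: the pipeline recovers the planted supply~TE correlation", {
  spec <- toy_model_spec(yields = c(A = 3, B = 2, C = 1.2, D = 0.6))
  m <- build_toy_model(spec)
  prot <- gen_proteome(800, spec, seed = 40, length = 200)
  sup <- supply_table(m, toy_aa_map(m), prot)
  params <- planted_params(target_spearman_supply_te = 0.30,
                           n_genes = 800L, seed = 41)
  expr <- gen_expression(sup$supply, params)
  expr$gene_id <- sup$protein_id
  gm <- gene_metrics(expr)
  gt <- build_gene_table(sup, gm)
  gt <- gt[gt$passed_te_filter, ]
  est <- spearman(gt$supply, gt$te)$r
  expect_lt(abs(est - 0.30), 0.08)  # n = 800 here; tighter bound at n = 2000
})
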