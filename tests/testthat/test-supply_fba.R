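test_that("TOY1 growth and supplies match the hand-derived LP values", {
  m <- toy1_model()
  map <- toy_aa_map(m)
  mu <- max_growth(m)
  expect_equal(mu, 20 / 3, tolerance = 1e-9)
  expect_equal(amino_acid_supply(m, map, c(A = 1), beta = 0.3, mu = mu)$supply,
               14, tolerance = 1e-6)
  expect_equal(amino_acid_supply(m, map, c(B = 1), beta = 0.3, mu = mu)$supply,
               7, tolerance = 1e-6)
  expect_equal(amino_acid_supply(m, map, c(A = 0.5, B = 0.5), beta = 0.3,
                                 mu = mu)$supply,
               28 / 3, tolerance = 1e-6)
})

test_that("zero substrate uptake gives zero growth", {
  m <- set_bounds(toy1_model(), "EX_substrate", lower_bound = 0)
  expect_equal(max_growth(m), 0, tolerance = 1e-9)
})

test_that("partial biomass scales only amino-acid coefficients", {
  spec <- toy_model_spec(yields = c(A = 2, B = 1),
                         extra_biomass_components = c(atp = 59.81))
  m <- build_toy_model(spec)
  map <- toy_aa_map(m)
  pm <- make_partial_biomass(m, map, beta = 0.3)
  bio <- pm$reactions[[match("BIOMASS",
                             vapply(pm$reactions, `[[`, character(1), "id"))]]
  expect_equal(bio$stoichiometry[["aa_A"]], -0.3)
  expect_equal(bio$stoichiometry[["aa_B"]], -0.3)
  expect_equal(bio$stoichiometry[["atp"]], -59.81)  # untouched
  # beta = 1 is the identity
  pm1 <- make_partial_biomass(m, map, beta = 1)
  expect_equal(stoich_matrix(pm1), stoich_matrix(m))
  # the original model is untouched (copy semantics)
  bio0 <- m$reactions[[match("BIOMASS",
                             vapply(m$reactions, `[[`, character(1), "id"))]]
  expect_equal(bio0$stoichiometry[["aa_A"]], -1)
  # an aa metabolite absent from the biomass reaction warns but does not error
  map2 <- aa_map(c("A", "B", "S"), c("aa_A", "aa_B", "substrate"), model = m)
  expect_warning(make_partial_biomass(m, map2, 0.3), "substrate")
})

test_that("protein sink consumes frequencies exactly and validates input", {
  m <- toy1_model()
  map <- toy_aa_map(m)
  ws <- make_protein_sink(m, map, c(A = 0.5, B = 0.5))
  sink <- ws$model$reactions[[length(ws$model$reactions)]]
  expect_equal(sort(sink$stoichiometry),
               sort(c(aa_A = -0.5, aa_B = -0.5)))
  expect_identical(sink$lower_bound, 0)
  expect_identical(sink$upper_bound, Inf)
  single <- make_protein_sink(m, map, c(A = 1))$model
  expect_equal(single$reactions[[length(single$reactions)]]$stoichiometry,
               c(aa_A = -1))
  expect_error(make_protein_sink(m, map, c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(make_protein_sink(m, map, c(A = 0.5, Z = 0.5)), "Z")
  # frequencies from a sequence feed the sink coefficients exactly
  fr <- aa_frequencies("AAAB", alphabet = c("A", "B"))
  ws2 <- make_protein_sink(m, map, fr)
  sink2 <- ws2$model$reactions[[length(ws2$model$reactions)]]
  expect_equal(sink2$stoichiometry[["aa_A"]], -0.75)
  expect_equal(sink2$stoichiometry[["aa_B"]], -0.25)
})

test_that("supply_table is deterministic, ordered, and duplicate proteins agree", {
  m <- toy1_model()
  map <- toy_aa_map(m)
  prot <- list(allA = c(A = 1), allB = c(B = 1), half = c(A = 0.5, B = 0.5),
               allA2 = c(A = 1))
  tab <- supply_table(m, map, prot)
  expect_identical(tab$protein_id, names(prot))
  expect_equal(tab$supply, c(14, 7, 28 / 3, 14), tolerance = 1e-6)
  expect_true(all(tab$mu == 20 / 3))
})

test_that("supply ranking is invariant to the basal level (model linearity)", {
  spec <- random_toy_spec(11, n_aa = 4)
  m <- build_toy_model(spec)
  map <- toy_aa_map(m)
  prot <- lapply(1:15, function(i) random_freq(names(spec$yields), i))
  names(prot) <- paste0("p", 1:15)
  ranks <- sapply(c(0.1, 0.3, 0.5, 0.7), function(beta) {
    rank(supply_table(m, map, prot, beta = beta)$supply)
  })
  for (j in 2:ncol(ranks)) {
    expect_equal(stats::cor(ranks[, 1], ranks[, j], method = "spearman"), 1)
  }
})

test_that("more substrate never decreases supply (monotonicity)", {
  spec <- random_toy_spec(3, n_aa = 3)
  prot <- lapply(1:6, function(i) random_freq(names(spec$yields), 100 + i))
  names(prot) <- paste0("p", 1:6)
  sup <- lapply(c(5, 10, 20), function(u) {
    m <- build_toy_model(spec)
    supply_table(m, toy_aa_map(m), prot, uptake = u,
                 exchange_id = "EX_substrate")$supply
  })
  expect_true(all(sup[[2]] >= sup[[1]] - 1e-8))
  expect_true(all(sup[[3]] >= sup[[2]] - 1e-8))
})

test_that("fixing the partial biomass at mu stays feasible for beta < 1", {
  for (seed in c(2, 5, 9)) {
    spec <- random_toy_spec(seed)
    m <- build_toy_model(spec)
    map <- toy_aa_map(m)
    mu <- max_growth(m)
    fr <- random_freq(names(spec$yields), seed + 50)
    res <- amino_acid_supply(m, map, fr, beta = 0.5, mu = mu)
    expect_identical(res$status, "optimal")
    expect_gte(res$supply, 0)
  }
})
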