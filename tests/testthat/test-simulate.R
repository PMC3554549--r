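# Simulation framework: AFS models, genotypes, etiologies, traits,
# extreme-phenotype study construction.

test_that("EA-like spectrum is almost entirely rare", {
  maf <- sample_site_frequencies(afs_model("EA-like"), 10000, seed = 1)
  expect_true(all(maf > 0 & maf <= 0.5))
  expect_gte(mean(maf < 0.001), 0.90)
})

test_that("AA-like spectrum occupies rare, low-frequency and common bands", {
  maf <- sample_site_frequencies(afs_model("AA-like"), 10000, seed = 2)
  expect_gt(mean(maf < 0.01), 0)
  expect_gt(mean(maf >= 0.01 & maf <= 0.05), 0)
  expect_gt(mean(maf > 0.05), 0)
})

test_that("frequency sampling is seed-deterministic", {
  m1 <- sample_site_frequencies(afs_model("AA-like"), 500, seed = 9)
  m2 <- sample_site_frequencies(afs_model("AA-like"), 500, seed = 9)
  expect_identical(m1, m2)
})

test_that("genotypes are binomial draws in {0,1,2}", {
  G <- simulate_genotypes(rep(0.5, 4), 5000, seed = 3)
  expect_true(all(G %in% 0:2))
  het <- mean(G == 1L)
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / length(G)))
  expect_identical(simulate_genotypes(c(0.1, 0.2), 10, seed = 4),
                   simulate_genotypes(c(0.1, 0.2), 10, seed = 4))
  expect_error(simulate_genotypes(0.6, 10))
  expect_error(simulate_genotypes(0.1, 1))
})

test_that("etiology presets encode the documented causal rules", {
  et <- etiology_config("rare")
  expect_equal(et$causal_maf_range, c(0, 0.01))
  expect_equal(et$effect_size_deleterious, 0.5)
  kp <- etiology_config("keyregion_protect")
  expect_true(kp$key_region && kp$protective)
  expect_lt(kp$effect_size_protective, 0)
  expect_gt(kp$effect_size_deleterious, 0)
  expect_error(etiology_config("rare_protect", effect_size_protective = 0.5))
})

test_that("effect assignment respects eligibility, key regions and nulls", {
  v <- data.frame(maf = c(0.10, 0.005, 0.002), in_key = c(TRUE, TRUE, FALSE))
  eff <- assign_causal_effects(v, etiology_config("rare", null_fraction = 0),
                               seed = 1)
  expect_equal(eff[1], 0)            # MAF 0.10 ineligible under rare
  expect_equal(eff[2:3], c(0.5, 0.5))
  effk <- assign_causal_effects(v, etiology_config("key_region",
                                                   null_fraction = 0),
                                seed = 1)
  expect_equal(effk[3], 0)           # eligible MAF but outside key region
  expect_equal(effk[2], 1.0)
  effn <- assign_causal_effects(v, etiology_config("rare", null_fraction = 1),
                                seed = 1)
  expect_true(all(effn == 0))
})

test_that("common etiology designates a single causal variant", {
  v <- data.frame(maf = c(0.2, 0.3, 0.004), in_key = FALSE)
  eff <- assign_causal_effects(v, etiology_config("common"), seed = 2)
  expect_equal(sum(eff != 0), 1L)
  expect_true(which(eff != 0) %in% 1:2)
  expect_warning(assign_causal_effects(data.frame(maf = 0.001),
                                       etiology_config("common"), seed = 1),
                 "no variant eligible")
})

test_that("protective etiologies mix negative and positive effects", {
  set.seed(3)
  v <- data.frame(maf = runif(400, 1e-4, 0.009), in_key = FALSE)
  eff <- assign_causal_effects(v, etiology_config("rare_protect"), seed = 4)
  expect_gt(sum(eff > 0), 0)
  expect_gt(sum(eff < 0), 0)
  expect_gt(sum(eff == 0), 0)  # null fraction leaves some without effect
  expect_equal(sort(unique(eff)), c(-0.5, 0, 0.5))
})

test_that("traits are Gaussian around the genetic mean shift", {
  phi0 <- simulate_trait(matrix(0L, 1e5, 2), c(0.5, 0.5), seed = 5)
  expect_lt(abs(mean(phi0)), 4 / sqrt(1e5))
  expect_lt(abs(var(phi0) - 1), 0.02)
  row <- matrix(c(2L, 1L), 1e5, 2, byrow = TRUE)
  phi <- simulate_trait(row, c(0.25, 0.25), seed = 6)
  expect_lt(abs(mean(phi) - 0.75), 4 / sqrt(1e5))
  phip <- simulate_trait(matrix(c(1L, 0L), 1, 2), c(-0.5, 0.3), seed = 7)
  expect_length(phip, 1L)
})

test_that("extreme-phenotype pools follow the stated fractions", {
  set.seed(8)
  pop <- simulate_genotypes(rep(0.05, 3), 10000)
  tr <- rnorm(10000)
  st <- draw_case_control_study(pop, tr, 100, 2500, seed = 9)
  expect_length(st$case_idx, 100L)   # affected pool is exactly 1% of 10000
  expect_length(st$ctrl_idx, 2500L)  # unaffected pool is 25%
  expect_length(intersect(st$case_idx, st$ctrl_idx), 0L)
  expect_error(draw_case_control_study(pop, tr, 200, 100, seed = 1),
               "affected pool")
  expect_error(draw_case_control_study(pop, tr, 50, 2600, seed = 1),
               "unaffected pool")
  # cases come from the top tail, controls from the bottom tail
  expect_true(min(tr[st$case_idx]) >= quantile(tr, 0.99))
  expect_true(max(tr[st$ctrl_idx]) <= quantile(tr, 0.25))
})

test_that("monomorphic sites are retained and flagged", {
  pop <- cbind(simulate_genotypes(rep(0.2, 2), 1000, seed = 10),
               0L)  # a site with no alternate alleles anywhere
  st <- draw_case_control_study(pop, rnorm(1000), 5, 5, seed = 11)
  expect_length(st$monomorphic, 3L)
  expect_true(st$monomorphic[3])
})

test_that("gene-set populations put effects only in causal genes", {
  pop <- build_gene_set_population(9, 200, rep(c(TRUE, FALSE), c(3, 6)),
                                   etiology_config("rare"),
                                   afs_model("AA-like", sites_per_gene = 20),
                                   seed = 12)
  genes_with_effect <- unique(pop$variants$gene[pop$effects != 0])
  expect_length(genes_with_effect, 3L)
  expect_true(all(genes_with_effect %in% sprintf("gene%03d", 1:3)))
  pop2 <- build_gene_set_population(9, 200, rep(c(TRUE, FALSE), c(3, 6)),
                                    etiology_config("rare"),
                                    afs_model("AA-like", sites_per_gene = 20),
                                    seed = 12)
  expect_identical(pop$G, pop2$G)
  expect_identical(pop$traits, pop2$traits)
})

test_that("without causal genes the trait is standard normal", {
  pop <- build_gene_set_population(4, 20000, rep(FALSE, 4),
                                   etiology_config("rare"),
                                   afs_model("AA-like", sites_per_gene = 5),
                                   seed = 13)
  expect_true(all(pop$effects == 0))
  expect_lt(abs(mean(pop$traits)), 4 / sqrt(20000))
  expect_lt(abs(var(pop$traits) - 1), 0.03)
})

test_that("key-region genes use the segmented geometry", {
  sc <- bomp_scenario(n_genes = 1, etiology = etiology_config("key_region"),
                      population_size = 5000, n_case = 25, n_ctrl = 25)
  st <- simulate_study(sc, seed = 14)
  expect_equal(unname(st$gene_lengths[1]), 1000L)
  v <- st$genotypes$variants
  causal <- v[st$effects != 0, ]
  expect_true(all(causal$in_key))
  expect_true(all(causal$maf <= 0.01))
})

test_that("simulated studies are deterministic in (scenario, seed)", {
  sc <- bomp_scenario(n_genes = 2, n_causal = 1, population_size = 5000,
                      n_case = 20, n_ctrl = 20)
  s1 <- simulate_study(sc, seed = 15)
  s2 <- simulate_study(sc, seed = 15)
  expect_identical(s1$genotypes$G, s2$genotypes$G)
  expect_identical(s1$traits, s2$traits)
  expect_false(identical(s1$genotypes$G,
                         simulate_study(sc, seed = 16)$genotypes$G))
})

test_that("infeasible scenario pools are rejected up front", {
  expect_error(bomp_scenario(population_size = 5000, n_case = 200,
                             n_ctrl = 100),
               "affected pool")
})
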