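# Wright-Fisher two-strain generator: determinism, degenerate inputs,
# ground-truth bookkeeping and the mutation-influx expectation.

test_that("identical seed and config reproduce the study exactly", {
  cfg <- sim_config(arm_names = c("2L", "X"), genome_length = 2e4,
                    n_genes = 4, generations = 60, mutation_rate = 2e-7,
                    seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(as.character(a$outgroup), as.character(b$outgroup))
  expect_identical(a$genes, b$genes)
})

test_that("no mutational input yields no variants and an identical outgroup", {
  cfg <- sim_config(arm_names = "2L", genome_length = 5e3, n_genes = 2,
                    generations = 0, mutation_rate = 0,
                    outgroup_divergence = 0, seed = 3)
  sim <- simulate_study(cfg)
  expect_identical(nrow(sim$sites), 0L)
  expect_identical(nrow(sim$truth), 0L)
  expect_identical(as.character(sim$reference), as.character(sim$outgroup))
})

test_that("invalid configurations are rejected with a message", {
  expect_error(sim_config(pop_size = 0), "pop_size")
  expect_error(sim_config(generations = -1), "generations")
  expect_error(sim_config(mutation_rate = 1.5), "rates outside")
  expect_error(sim_config(genome_length = 1e4,
                          selected_loci = data.frame(arm = "2L", pos = 2e4,
                                                     s = 0.1)),
               "outside genome")
  expect_error(sim_config(selected_loci = data.frame(arm = "nope", pos = 10,
                                                     s = 0.1)),
               "unknown arm")
})

test_that("origin labels are consistent with the emitted outgroup state", {
  cfg <- sim_config(arm_names = c("2L", "2R"), genome_length = 5e4,
                    n_genes = 0, generations = 80, mutation_rate = 2e-7,
                    outgroup_divergence = 0.05, seed = 7)
  sim <- simulate_study(cfg)
  tr <- sim$truth
  expect_gt(nrow(tr), 0)
  # new => allele absent from the outgroup at that site; old => equals it
  expect_true(all(tr$alt[tr$origin == "new"] !=
                    tr$outgroup_allele[tr$origin == "new"]))
  expect_true(all(tr$alt[tr$origin == "old"] ==
                    tr$outgroup_allele[tr$origin == "old"]))
  # emitted site records mirror the truth labels
  expect_true(all(sim$sites$origin %in% c("old", "new")))
})

test_that("selected alleles exist only in strain R and respond to selection", {
  cfg <- sim_config(arm_names = "2L", genome_length = 5e4, n_genes = 0,
                    generations = 120, mutation_rate = 1e-8,
                    selected_loci = data.frame(arm = "2L", pos = 25000,
                                               s = 0.2),
                    seed = 11)
  sim <- simulate_study(cfg)
  sel <- sim$truth[sim$truth$selected, ]
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$true_freq_C, 0)       # never introduced into C
  expect_gt(sel$true_freq_R, 0.9)            # driven toward fixation
})

test_that("new-mutation influx matches the 2*N*mu*L*t expectation", {
  # Poisson influx: mean 2*100*1e-8*1e6 = 2 per strain per generation,
  # so 1000 expected events per strain over t = 500
  per_strain <- vapply(1:20, function(s) {
    cfg <- sim_config(arm_names = "2L", genome_length = 1e6, n_genes = 0,
                      pop_size = 100, generations = 500,
                      mutation_rate = 1e-8, outgroup_divergence = 0,
                      dip_fraction = 0, seed = s)
    sum(simulate_study(cfg)$n_new_mutations) / 2
  }, numeric(1))
  expect_lt(abs(mean(per_strain) - 1000), 3 * sqrt(1000) / sqrt(20))
})

test_that("quality profiles respect fail_fraction ground truth", {
  cfg <- sim_config(arm_names = "2L", genome_length = 5e4, n_genes = 0,
                    generations = 60, mutation_rate = 4e-7, seed = 5)
  sim <- simulate_study(cfg)

  q0 <- write_quality_profiles(sim$sites, fail_fraction = 0, seed = 1)
  expect_false(any(q0$injected_fail))
  expect_true(all(q0$central_q >= 20))
  expect_true(all(!q0$true_fail_central & !q0$true_fail_flank))

  q1 <- write_quality_profiles(sim$sites, fail_fraction = 1,
                               fail_mode = "central_q", seed = 1)
  expect_true(all(q1$injected_fail))
  expect_true(all(q1$fail_rule == "central_quality"))
  expect_true(all(q1$central_q == 19L))
})

test_that("injected failure fraction is binomially consistent", {
  sites <- make_sites("2L", seq(100, by = 50, length.out = 1000))
  q <- write_quality_profiles(sites, fail_fraction = 0.3, seed = 99)
  p_hat <- mean(q$injected_fail)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})
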