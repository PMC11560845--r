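ancestral <- function() transmission_params(g = 0.063, e = 0.69, p0 = 0.05)
evolved <- function() transmission_params(g = 0.75, e = 0.69, p0 = 0.5)

test_that("generate_experiment is deterministic under a fixed seed", {
  tc <- truth_config(ancestral(), n_lines = 3, n_rounds = 3, seed = 42)
  a <- generate_experiment(tc)
  b <- generate_experiment(tc)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$alleles, b$alleles)
  # and genuinely different under another seed
  c <- generate_experiment(truth_config(ancestral(), n_lines = 3,
                                        n_rounds = 3, seed = 43))
  expect_false(identical(a$measurements, c$measurements))
})

test_that("generated measurements obey the schema and the design", {
  tc <- truth_config(ancestral(), n_lines = 4, n_rounds = 3, seed = 5)
  out <- generate_experiment(tc)
  m <- out$measurements
  expect_equal(sort(unique(m$line_id)), paste0("L", 1:4))
  expect_equal(sort(unique(m$round)), 1:3)
  # round-1 positive arm uses 5 plates of 96 wells, later rounds 3 plates
  expect_true(all(m$wells_sorted_pos[m$round == 1] == 480))
  expect_true(all(m$wells_sorted_pos[m$round > 1] == 288))
  expect_true(all(m$wells_sorted_neg == 96))
  expect_true(all(m$germinated_day1_pos <= m$germinated_day2_pos))
  expect_true(all(m$germinated_day2_pos <= m$wells_sorted_pos))
  expect_true(all(m$facs_positive <= m$facs_analyzed))
  # manifest records the seed and truth separately from the data
  expect_equal(out$manifest$seed, 5)
  expect_equal(out$manifest$truth$params$g, 0.063)
})

test_that("p0 = 0 gives an all-zero positive fraction", {
  tc <- truth_config(transmission_params(g = 0.5, e = 0.69, p0 = 0),
                     n_lines = 2, n_rounds = 3, selection_mode = "none",
                     seed = 9)
  out <- generate_experiment(tc)
  expect_true(all(out$measurements$facs_positive == 0))
})

test_that("pooling merges the weakest lines after the configured round", {
  tc <- truth_config(evolved(), n_lines = 5, n_rounds = 4,
                     pool_after_round = 2, n_kept_lines = 2, seed = 31)
  out <- generate_experiment(tc)
  m <- out$measurements
  expect_equal(length(unique(m$line_id[m$round <= 2])), 5L)
  after <- unique(m$line_id[m$round > 2])
  expect_equal(length(after), 3L)
  expect_true("LP" %in% after)
})

test_that("fitness contrast between regimes mirrors the evolved experiment", {
  # ancestral-like truth vs evolved-like truth: beyond round 1 the evolved
  # regime's fitness index dominates in every round
  anc <- generate_experiment(truth_config(ancestral(), n_lines = 3,
                                          n_rounds = 4, seed = 101))
  evo <- generate_experiment(truth_config(evolved(), n_lines = 3,
                                          n_rounds = 4, seed = 101))
  fa <- fitness_table(anc$measurements)
  fe <- fitness_table(evo$measurements)
  for (r in 2:4) {
    expect_gt(min(fe$fitness_index[fe$round == r]),
              max(fa$fitness_index[fa$round == r]))
  }
})

test_that("allele tables contain the configured sweeps", {
  tc <- truth_config(evolved(), n_lines = 3, n_rounds = 10, seed = 77)
  out <- generate_experiment(tc)
  al <- out$alleles
  expect_true(all(al$frequency >= 0 & al$frequency <= 1))
  swept <- filter_sweeping_mutations(al)
  sm <- tc$sweep_model
  expected <- sm$mutation_id[!sm$present_in_ancestor &
                               plogis(sm$s * (10 - sm$midpoint_round)) > 0.6]
  expect_true(all(expected %in% swept))
  expect_false("mut_ancestral" %in% swept)
})

test_that("generate_spore_stack: constructive ground truth and determinism", {
  # zero bacteria, zero noise: background only
  z <- generate_spore_stack(0, seed = 1)
  expect_equal(z$truth_voxels, 0)
  expect_equal(quantify_load(z$stack, threshold = z$stack$intensities[1])$n_voxels,
               0)
  # no blur, no noise: quantified count equals constructed truth exactly
  gs <- generate_spore_stack(5, seed = 2)
  expect_gt(gs$truth_voxels, 0)
  lr <- quantify_load(gs$stack, threshold = 100)
  expect_equal(lr$n_voxels, gs$truth_voxels)
  expect_lte(lr$n_components, 5)
  # determinism
  gs2 <- generate_spore_stack(5, seed = 2)
  expect_identical(gs$stack$intensities, gs2$stack$intensities)
  # overcrowding errors out rather than looping forever
  expect_error(generate_spore_stack(500, shape = c(8, 16, 16), seed = 3),
               "overcrowded")
})

test_that("noisy stacks stay within 10% of truth at SNR >= 10", {
  for (s in 1:5) {
    gs <- generate_spore_stack(4, psf_sigma = 0.1, background = 10,
                               signal = 200, poisson_noise = TRUE,
                               gaussian_sd = 3, seed = 300 + s)
    lr <- quantify_load(gs$stack, threshold = otsu_threshold(gs$stack))
    expect_lt(abs(lr$n_voxels - gs$truth_voxels) / gs$truth_voxels, 0.10)
  }
})

test_that("generate_facs_intensities links load to intensity", {
  pool <- spore_pool(500, 500)
  fx <- generate_facs_intensities(pool, load_model(), seed = 4)
  expect_equal(nrow(fx), 1000)
  expect_equal(sum(fx$positive), 500)
  expect_gt(median(fx$intensity[fx$positive]),
            median(fx$intensity[!fx$positive]))
  # negatives only: all intensities at baseline level
  neg <- generate_facs_intensities(spore_pool(0, 300), load_model(), seed = 5)
  expect_lt(max(neg$intensity), 100 + 5 * 20)
  # factor = 0: positives indistinguishable in expectation
  flat <- generate_facs_intensities(pool, load_model(intensity_per_load = 0),
                                    seed = 6)
  expect_lt(abs(mean(flat$intensity[flat$positive]) -
                  mean(flat$intensity[!flat$positive])), 15)
  # doubling the load median shifts positive median intensity ~2x
  lo <- generate_facs_intensities(pool, load_model(median = 2), seed = 7)
  hi <- generate_facs_intensities(pool, load_model(median = 4), seed = 7)
  ratio <- (median(hi$intensity[hi$positive]) - 100) /
    (median(lo$intensity[lo$positive]) - 100)
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("intensity gates are monotone in true load", {
  set.seed(21)
  fx <- generate_facs_intensities(spore_pool(300, 0), load_model(), seed = 21)
  bins <- classify_intensity_bins(fx$intensity)
  means <- tapply(fx$load, bins, mean)
  expect_true(means[["low"]] < means[["medium"]] &&
                means[["medium"]] < means[["high"]])
})

test_that("spore aging decays positive-spore germination", {
  fresh <- truth_config(evolved(), n_lines = 2, n_rounds = 2, seed = 55)
  aged <- truth_config(evolved(), n_lines = 2, n_rounds = 2, seed = 55,
                       aging_days = 27)
  gf <- fitness_table(generate_experiment(fresh)$measurements)
  ga <- fitness_table(generate_experiment(aged)$measurements)
  expect_lt(mean(ga$germination_pos), 0.1)
  expect_gt(mean(gf$germination_pos), 0.5)
  # negatives are unaffected by storage
  expect_equal(mean(ga$germination_neg), mean(gf$germination_neg),
               tolerance = 0.2)
})
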