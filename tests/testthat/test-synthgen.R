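test_that("generators are bit-identical under a fixed seed", {
  cfg <- synth_config(seed = 11)
  d1 <- gen_cleavage_dataset(cfg, 200, 10)
  d2 <- gen_cleavage_dataset(cfg, 200, 10)
  expect_identical(d1, d2)

  truth <- default_stability_truth()
  expect_identical(gen_melt_curves(truth, noise_sd = 10, seed = 5),
                   gen_melt_curves(truth, noise_sd = 10, seed = 5))
  expect_identical(gen_dls_trace(seed = 5, noise_sd = 0.2),
                   gen_dls_trace(seed = 5, noise_sd = 0.2))
  expect_identical(gen_tht_trace(seed = 5, noise_sd = 2),
                   gen_tht_trace(seed = 5, noise_sd = 2))
})

test_that("synth_config validates motifs, background and noise levels", {
  expect_error(synth_config(motifs = list(b = list("9" = c(K = 1)))),
               "within 1..8")
  expect_error(synth_config(motifs = list(b = list("4" = c(X = 1)))),
               "canonical")
  expect_error(synth_config(motifs = list(b = list("4" = c(K = 1.4)))),
               "at most 1")
  bad <- human_aa_freq; bad[1] <- bad[1] + 0.01
  expect_error(synth_config(background = bad), "sum to 1")
  expect_error(synth_config(noise_sd_tht = -1), "nonnegative")
})

test_that("degenerate motif forces the planted residue at P1", {
  cfg <- synth_config(seed = 2, n_substrates = 50,
                      motifs = list(enz = list("4" = c(K = 1))))
  ds <- gen_cleavage_dataset(cfg, 50, 0)
  expect_identical(nrow(ds$windows), 50L)
  expect_true(all(substr(ds$windows$window, 4, 4) == "K"))
  ## n_fragments = 0: empty fragment list, sequence still returned
  expect_identical(nrow(ds$fragments), 0L)
  expect_identical(nchar(ds$sequence), 50L)
})

test_that("planted P1 frequency falls inside its binomial 99% band", {
  prob <- 0.8
  cfg <- synth_config(seed = 9, n_substrates = 200,
                      motifs = list(enz = list("4" = c(K = prob))))
  ds <- gen_cleavage_dataset(cfg, 50, 0)
  k <- sum(substr(ds$windows$window, 4, 4) == "K")
  ## effective rate includes background K draws on the non-motif branch
  p_eff <- prob + (1 - prob) * human_aa_freq[["K"]]
  bounds <- stats::qbinom(c(0.005, 0.995), 200, p_eff)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("fragment edges sit on motif-matched cut sites", {
  cfg <- synth_config(seed = 21)
  ds <- gen_cleavage_dataset(cfg, 400, 25)
  expect_gt(nrow(ds$fragments), 0)
  cuts <- ds$truth$cut_sites
  aa <- strsplit(ds$sequence, "")[[1]]
  ## every cut matches one of the planted motifs (R at P1 or F at P1')
  expect_true(all(aa[cuts] == "R" | aa[cuts + 1L] == "F"))
  ## interior fragment termini coincide with cuts
  int <- ds$fragments[ds$fragments$start > 1 &
                        ds$fragments$end < nchar(ds$sequence), ]
  expect_true(all((int$start - 1L) %in% cuts))
  expect_true(all(int$end %in% cuts))
})

test_that("noiseless melt curves equal the two-state signal model exactly", {
  truth <- default_stability_truth()
  cv <- gen_melt_curves(truth, urea_grid = c(0, 2), noise_sd = 0)
  expect_length(cv, 2L)
  for (c1 in cv) {
    expect_equal(c1$I330, signal_model(truth, c1$T_C, c1$urea, 330),
                 tolerance = 1e-12)
    expect_equal(c1$I350, signal_model(truth, c1$T_C, c1$urea, 350),
                 tolerance = 1e-12)
  }
  ## the protocol grid yields one curve family per urea per capillary
  cv9 <- gen_melt_curves(truth, noise_sd = 0, n_capillaries = 2)
  expect_length(cv9, 18L)
  expect_length(unique(vapply(cv9, `[[`, character(1), "capillary_id")),
                18L)
})

test_that("zero-urea fluorescence midpoint sits at the planted Tm", {
  truth <- default_stability_truth(Tm = 50)
  Tg <- seq(30, 70, by = 0.005)
  cv <- gen_melt_curves(truth, urea_grid = 0, T_grid = Tg,
                        noise_sd = 0)[[1]]
  ## locate where the unfolded population crosses one half: the signal
  ## equals the mean of the two baselines there
  b <- truth$baselines[["330"]]
  mid <- ((b[["f_int"]] + b[["f_slope"]] * Tg) +
            (b[["u_int"]] + b[["u_slope"]] * Tg)) / 2
  i <- which.min(abs(cv$I330 - mid))
  expect_equal(Tg[i], 50, tolerance = 0.01)
})

test_that("DLS generator places the onset by the divergence rule", {
  flat <- gen_dls_trace(Tagg_true = NULL, growth_amplitude = 0,
                        noise_sd = 0)
  expect_equal(diff(range(flat$radius -
                            (3 + 0.01 * (flat$T_C - flat$T_C[1])))), 0,
               tolerance = 1e-12)
  tr <- gen_dls_trace(Tagg_true = 55, noise_sd = 0)
  truth <- attr(tr, "truth")
  ## growth contribution at the planted onset equals 0.5% of baseline
  rb <- 3 + 0.01 * (55 - tr$T_C[1])
  g55 <- truth$growth_amplitude /
    (1 + exp(-(55 - truth$centre) / truth$growth_width))
  expect_equal(g55 / rb, 0.005, tolerance = 1e-9)
  ## micron-scale amplitude reaches the >1000 nm category at scan end
  expect_gt(max(tr$radius), 950)
})

test_that("ThT generator evaluates the printed sigmoid", {
  ## flat-baseline case: intensity at t50 is y_i + y_f/2
  tr <- gen_tht_trace(list(y_i = 1, m_i = 0, y_f = 9, m_f = 0,
                           t50 = 10, k = 1),
                      t_grid = seq(0, 20, by = 0.5), noise_sd = 0)
  expect_equal(tr$intensity[tr$t == 10], 1 + 9 / 2, tolerance = 1e-12)
  ## y_f = 0: flat curve, fold increase 1
  fl <- gen_tht_trace(list(y_i = 5, m_i = 0, y_f = 0, m_f = 0,
                           t50 = 10, k = 1), noise_sd = 0)
  expect_equal(fold_increase(fl), 1)
  expect_error(gen_tht_trace(list(y_i = 1, m_i = 0, y_f = 9, m_f = 0,
                                  t50 = 10, k = -1)), "positive")
})

test_that("residual spread converges to the requested noise level", {
  truth <- default_stability_truth()
  clean <- gen_melt_curves(truth, urea_grid = 2,
                           T_grid = seq(20, 70, length.out = 2000),
                           noise_sd = 0)[[1]]
  noisy <- gen_melt_curves(truth, urea_grid = 2,
                           T_grid = seq(20, 70, length.out = 2000),
                           noise_sd = 25, seed = 13)[[1]]
  expect_equal(stats::sd(noisy$I330 - clean$I330), 25, tolerance = 0.1)
  expect_equal(stats::sd(noisy$I350 - clean$I350), 25, tolerance = 0.1)

  t2 <- gen_tht_trace(t_grid = seq(0, 50, length.out = 3000),
                      noise_sd = 2, seed = 4)
  t0 <- gen_tht_trace(t_grid = seq(0, 50, length.out = 3000),
                      noise_sd = 0)
  expect_equal(stats::sd(t2$intensity - t0$intensity), 2, tolerance = 0.1)
})
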