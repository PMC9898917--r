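test_that("PSSM counts, pseudocount and log-odds follow the additive scheme", {
  ## uniform windows + uniform background -> every cell log(1) = 0
  p_unif <- build_pssm(uniform_windows(), pseudocount = 5,
                       background = uniform_background())
  expect_equal(max(abs(p_unif$log_odds)), 0, tolerance = 1e-12)
  expect_equal(p_unif$n_windows, 20L)

  ## 20 windows all with 'A' at P1: direct arithmetic
  ## p = (20 + 5)/(20 + 100), log-odds = log(p / 0.05) = 1.427116
  w <- vapply(1:20, function(i) {
    s <- rep("G", 8L); s[4] <- "A"; paste(s, collapse = "")
  }, character(1L))
  p <- build_pssm(w, pseudocount = 5, background = uniform_background())
  expect_equal(p$log_odds["P1", "A"], log((20 + 5) / 120 / 0.05),
               tolerance = 1e-12)
  expect_equal(p$log_odds["P1", "A"], 1.427116, tolerance = 1e-6)

  ## pseudocount keeps every cell finite even for unseen residues
  expect_true(all(is.finite(p$log_odds)))

  ## probability reconstruction: background * exp(log_odds) sums to 1
  ## per position, for random training sets
  set.seed(42)
  for (rep in 1:5) {
    pr <- build_pssm(random_windows(30))
    probs <- sweep(exp(pr$log_odds), 2L, pr$background, "*")
    expect_equal(unname(rowSums(probs)), rep(1, 8L), tolerance = 1e-9)
  }

  expect_error(build_pssm(character()), "at least one")
  expect_error(build_pssm("SHORT"), "exactly 8")
  bad_bg <- uniform_background(); bad_bg["A"] <- 0
  bad_bg <- bad_bg / sum(bad_bg)
  expect_error(build_pssm(random_windows(5), background = bad_bg),
               "strictly positive")
})

test_that("score_sequence matches a brute-force window-sum oracle", {
  set.seed(7)
  for (rep in 1:10) {
    wins1 <- random_windows(15)
    wins2 <- random_windows(15)
    p1 <- build_pssm(wins1, protease_id = "b")
    p2 <- build_pssm(wins2, protease_id = "d")
    seqc <- random_sequence(60)
    prof <- score_sequence(seqc, list(p1, p2))

    oracle <- oracle_profile(seqc, list(
      oracle_pssm_logodds(wins1, 5, human_aa_freq),
      oracle_pssm_logodds(wins2, 5, human_aa_freq)))
    expect_equal(prof$scores$score, oracle[prof$scores$position],
                 tolerance = 1e-10)
  }
})

test_that("score profile respects validity, single-matrix and dominance cases", {
  p1 <- build_pssm(random_windows(10), protease_id = "solo")
  seqc <- random_sequence(40)
  prof <- score_sequence(seqc, p1)
  expect_identical(which(prof$valid_mask), 4:36)
  ## single PSSM: the max is the identity
  expect_equal(prof$scores$score, prof$scores$score_solo)

  ## a uniformly dominating matrix determines the profile alone
  p_hi <- p1; p_hi$log_odds <- p1$log_odds + 5; p_hi$protease_id <- "hi"
  prof2 <- score_sequence(seqc, list(p1, p_hi))
  expect_equal(prof2$scores$score, prof2$scores$score_hi)

  expect_warning(short <- score_sequence("ACDEFG", p1), "shorter than 8")
  expect_identical(nrow(short$scores), 0L)
})

test_that("logistic score-probability conversion is anchored and symmetric", {
  expect_equal(score_to_probability(0), 0.5)
  expect_equal(score_to_probability(1.5), 0.8175745, tolerance = 1e-7)
  s <- seq(-30, 30, by = 0.37)
  expect_equal(score_to_probability(s) + score_to_probability(-s),
               rep(1, length(s)), tolerance = 1e-12)
  ## stable in the tails
  expect_equal(score_to_probability(800), 1)
  expect_equal(score_to_probability(-800), 0)
  ## monotone
  expect_true(all(diff(score_to_probability(s)) > 0))
})

test_that("proximal mask implements the 2-before/1-after terminus rule", {
  expect_identical(proximal_mask(data.frame(start = integer(),
                                            end = integer()), 50),
                   rep(FALSE, 50))
  m <- proximal_mask(data.frame(start = 10, end = 30), 100)
  expect_identical(which(m), c(8:11, 29:32))
  ## N-terminal fragment clipped at the sequence start
  m2 <- proximal_mask(data.frame(start = 1, end = 20), 100)
  expect_identical(which(m2), c(1:2, 19:22))
  ## C-terminal clipping
  m3 <- proximal_mask(data.frame(start = 90, end = 100), 100)
  expect_identical(which(m3), c(88:91, 99:100))
  ## overlapping fragments merge
  m4 <- proximal_mask(data.frame(start = c(10, 12), end = c(30, 31)), 100)
  expect_identical(which(m4), c(8:13, 29:33))
  expect_error(proximal_mask(data.frame(start = 5, end = 200), 100),
               "out of bounds")
})

test_that("edge test gives exact enumeration p-values and agrees with wilcox.test", {
  prof <- list(scores = data.frame(position = 1:6,
                                   score = c(5, 6, 7, 1, 2, 3)),
               valid_mask = rep(TRUE, 6), seq_len = 6L)
  class(prof) <- "cleavage_profile"
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- edge_enrichment_test(prof, mask)
  expect_equal(res$U, 9)
  expect_equal(res$p_value, 1 / choose(6, 3))  # 0.05
  expect_identical(res$method, "exact")
  ## the flag is a strict p < alpha comparison, so exactly 0.05 misses it
  expect_false(res$significant)

  ## tie-free small samples match the exact wilcoxon distribution
  set.seed(3)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mine <- thagg:::mann_whitney_greater(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$U, unname(ref$statistic))
  }

  ## large samples: normal approximation with tie + continuity correction
  set.seed(4)
  x <- round(rnorm(20), 1); y <- round(rnorm(40), 1)  # forced ties
  mine <- thagg:::mann_whitney_greater(x, y)
  ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                            correct = TRUE)
  expect_identical(mine$method, "normal")
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)

  ## degenerate groups are an error
  prof_all <- prof; mask_all <- rep(TRUE, 6)
  expect_error(edge_enrichment_test(prof_all, mask_all), "non-empty")
  expect_true(res$U <= res$n_edge * res$n_nonedge)
})

test_that("U statistic counts pairwise wins with half-credit ties", {
  x <- c(3, 3, 5); y <- c(1, 3, 4)
  ## pairs: 3v1 w, 3v3 t, 3v4 l, 3v1 w, 3v3 t, 3v4 l, 5v1 w, 5v3 w, 5v4 w
  expect_equal(thagg:::u_statistic(x, y), 5 + 2 * 0.5)
})

test_that("contiguous proximal blocks keep nominal size on exchangeable scores", {
  ## the rank test itself is calibrated for any mask geometry as long as
  ## scores are exchangeable across positions; inflation seen on real
  ## profiles comes from window-overlap autocorrelation, not the test
  set.seed(55)
  rej <- mean(vapply(1:500, function(i) {
    sc <- rnorm(193)
    cuts <- sort(sample(4:189, 6))
    mask <- rep(FALSE, 200)
    for (cp in cuts) mask[max(1, cp - 2):min(200, cp + 2)] <- TRUE
    prof <- structure(list(
      scores = data.frame(position = 4:196, score = sc),
      valid_mask = c(rep(FALSE, 3), rep(TRUE, 193), rep(FALSE, 4)),
      seq_len = 200L), class = "cleavage_profile")
    edge_enrichment_test(prof, mask)$p_value < 0.05
  }, logical(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 500, 0.05) / 500
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})
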