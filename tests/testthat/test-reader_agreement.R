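ord5 <- default_scheme(5)$vertebrae$name

test_that("consensus level is the median under cranio-caudal ordering", {
  expect_equal(consensus_level(c("L4", "L4", "L4"), ord5), "L4")
  expect_equal(consensus_level(c("L3", "L4", "L5"), ord5), "L4")
  # with a 2-1 vote the median is the majority level
  expect_equal(consensus_level(c("L3", "L3", "L4"), ord5), "L3")
  expect_equal(consensus_level(c("L2", "L2", "L5"), ord5), "L2")
  expect_equal(consensus_level(c("L5", "L1", "L3", "L2", "L4"), ord5), "L3")
  expect_error(consensus_level(c("L3", "L4"), ord5),
               class = "spinecobb_unsupported_configuration")
  expect_error(consensus_level(c("L3", "L4", "L4", "L5"), ord5),
               class = "spinecobb_unsupported_configuration")
})

test_that("MAE handles identical, offset, and simulated inputs", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), list(mae = 0, sd = 0))
  r <- mae(c(0, 0), c(1, 3))
  expect_equal(r$mae, 2)
  expect_equal(r$sd, stats::sd(c(1, 3)))
})

test_that("ICC(2,1) matches frozen reference values and a hand ANOVA oracle", {
  tab <- rbind(c(9.1, 8.2, 9.9), c(11.5, 12.0, 11.1), c(6.3, 7.4, 6.9),
               c(14.2, 13.1, 15.0), c(10.0, 9.5, 10.8), c(7.7, 8.8, 7.1))
  r <- icc(tab)
  # frozen from an independent ICC(A,1) implementation on this table
  expect_equal(r$estimate, 0.923513, tolerance = 1e-6)
  expect_equal(r$lower, 0.7306828, tolerance = 1e-6)
  expect_equal(r$upper, 0.9878561, tolerance = 1e-6)
  expect_equal(r$band, "excellent")

  # independent mean-squares oracle via aov()
  df <- data.frame(y = as.vector(tab),
                   case = factor(rep(seq_len(nrow(tab)), ncol(tab))),
                   rater = factor(rep(seq_len(ncol(tab)), each = nrow(tab))))
  ms <- summary(stats::aov(y ~ case + rater, data = df))[[1]][["Mean Sq"]]
  n <- nrow(tab); k <- ncol(tab)
  oracle <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  expect_equal(r$estimate, oracle, tolerance = 1e-10)
  expect_equal(unname(r$ms), ms, tolerance = 1e-10)
})

test_that("ICC is permutation- and scale-invariant, and penalizes rater offsets", {
  set.seed(3)
  tab <- matrix(rnorm(8 * 3, 10, 4), 8, 3) + rnorm(8, 0, 3)
  base <- icc(tab)$estimate
  expect_equal(icc(tab[sample(8), sample(3)])$estimate, base, tolerance = 1e-12)
  expect_equal(icc(tab * 3.7)$estimate, base, tolerance = 1e-12)
  shifted <- tab; shifted[, 2] <- shifted[, 2] + 5
  expect_lt(icc(shifted)$estimate, base)

  # identical raters on varying cases: perfect reliability
  v <- c(3, 9, 4, 12, 7, 5)
  expect_equal(icc(cbind(v, v, v))$icc, 1)

  # pure rater noise with no case effect: ICC near 0, 0 inside the CI
  set.seed(4)
  noise <- matrix(rnorm(40 * 3), 40, 3)
  rn <- icc(noise)
  expect_lt(abs(rn$estimate), 0.3)
  expect_lt(rn$lower, 0.05)

  expect_error(icc(matrix(1, 3, 2)), class = "spinecobb_unsupported_configuration")
  bad <- matrix(rnorm(12), 6, 2); bad[2, 1] <- NA
  expect_error(icc(bad), class = "spinecobb_unsupported_configuration")
})

test_that("Bland-Altman recovers closed-form limits and is antisymmetric", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$bias, 0)
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$sd, 0)
  ba3 <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba3$bias, 3)
  expect_equal(ba3$lower, 3)
  expect_equal(ba3$upper, 3)

  set.seed(12)
  a <- rnorm(150, 20, 6)
  b <- a - rnorm(150, 3.2, 2.0)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 3.2, tolerance = 3 * 2 / sqrt(150))
  expect_equal(ba$upper - ba$lower, 2 * 1.96 * 2.0, tolerance = 0.8)

  rev <- bland_altman(b, a)
  expect_equal(rev$bias, -ba$bias)
  expect_equal(rev$upper - rev$bias, ba$upper - ba$bias)

  expect_error(bland_altman(1, 1), class = "spinecobb_no_measurement")
  expect_s3_class(plot_bland_altman(ba), "ggplot")
})

test_that("acceptance uses a strict 5-degree threshold and is monotone in tolerance", {
  manual <- data.frame(case = c("a", "b", "c"), source = "reader1",
                       top = "L2", bottom = "L4", angle = c(10, 15, 20))
  auto <- data.frame(case = c("a", "b", "c"), top = "L2", bottom = "L4",
                     angle = c(10, 10, 16))
  res <- acceptance_simulation(manual, auto)
  expect_equal(res$verdicts$accepted, c(TRUE, FALSE, TRUE)) # exactly 5 rejects
  expect_equal(res$fraction, 2 / 3)

  tols <- c(1, 3, 5, 7, 20)
  fr <- vapply(tols, function(t)
    acceptance_simulation(manual, auto, tolerance = t)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1)

  expect_error(acceptance_simulation(manual, auto[1:2, ]),
               class = "spinecobb_unavailable_level")
})

test_that("acceptance fraction matches the Gaussian closed form", {
  cfg <- phantom_config(endplate_tilts = cbind(c(10, 4, -4, -10), c(10, 4, -4, -10)),
                        spacing = std_spacing, id = "acc")
  tr <- phantom_truth(cfg)
  sigma <- 2
  manual <- do.call(rbind, lapply(1:300, function(s) {
    rd <- simulate_readers(tr, 3, angle_noise_sd = sigma, level_error_prob = 0, seed = s)
    rd$case <- paste0(rd$case, "-", s)
    rd
  }))
  auto <- unique(data.frame(case = manual$case, top = manual$top,
                            bottom = manual$bottom, angle = tr$max$angle))
  res <- acceptance_simulation(manual, auto, tolerance = 5)
  expected <- 2 * stats::pnorm(5 / sigma) - 1
  se <- sqrt(expected * (1 - expected) / nrow(manual))
  expect_lt(abs(res$fraction - expected), 4 * se + 0.005)
})

test_that("level agreement buckets sum the top and bottom offsets", {
  manual <- data.frame(case = rep(c("a", "b", "c", "d"), 2),
                       source = rep(c("r1", "r2"), each = 4),
                       top = c("L2", "L2", "L3", "L2", "L2", "L3", "L3", "L4"),
                       bottom = c("L4", "L3", "L4", "L5", "L4", "L3", "L5", "L5"),
                       angle = 10)
  ref <- data.frame(case = c("a", "b", "c", "d"), top = "L2", bottom = "L4")
  tab <- level_agreement_table(manual, ref, ord5)
  r1 <- tab[tab$source == "r1", ]
  # r1 distances: (L2,L4)=0, (L2,L3)=1, (L3,L4)=1, (L2,L5)=1
  d1 <- c(0, 1, 1, 1)
  expect_equal(unlist(r1[c("same", "one_level", "two_levels", "more")], use.names = FALSE),
               c(mean(d1 == 0), mean(d1 == 1), mean(d1 == 2), mean(d1 > 2)))
  r2 <- tab[tab$source == "r2", ]
  d2 <- c(0, 2, 2, 3)
  expect_equal(unlist(r2[c("same", "one_level", "two_levels", "more")], use.names = FALSE),
               c(mean(d2 == 0), mean(d2 == 1), mean(d2 == 2), mean(d2 > 2)))

  expect_error(level_agreement_table(manual, ref[1:3, ], ord5),
               class = "spinecobb_unavailable_level")
})

test_that("simulated reader panels bucket levels as the slip model predicts", {
  cfg <- phantom_config(endplate_tilts = cbind(c(2, 10, -10, -2), c(2, 10, -10, -2)),
                        spacing = std_spacing, id = "bucket")
  tr <- phantom_truth(cfg)
  p <- 0.3
  # one long panel drawn from a single RNG stream; each simulated reader is
  # an independent draw from the slip model, treated as one case
  rd <- simulate_readers(tr, 4000, angle_noise_sd = 0, level_error_prob = p,
                         seed = 31)
  manual <- data.frame(case = seq_len(nrow(rd)), source = "panel",
                       top = rd$top, bottom = rd$bottom, angle = rd$angle)
  ref <- data.frame(case = manual$case, top = tr$max$top, bottom = tr$max$bottom)
  tab <- level_agreement_table(manual, ref, ord5)
  # each endpoint slips one level with probability p
  expect_equal(tab$same, (1 - p)^2, tolerance = 0.06)
  expect_equal(tab$one_level, 2 * p * (1 - p), tolerance = 0.06)
  expect_equal(tab$two_levels, p^2, tolerance = 0.15)
})
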