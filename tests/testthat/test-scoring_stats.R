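test_that("keyword scoring is case/punctuation tolerant and credits once", {
  expect_equal(score_keywords(c("a", "b", "c"), c("a", "b", "c"))$n_correct, 3)
  expect_equal(score_keywords(character(0), c("a", "b"))$n_correct, 0)
  expect_equal(score_keywords(c("a", "c", "d"), c("a", "b", "c"))$n_correct, 2)
  expect_equal(score_keywords(c("The", "CAT!"), c("the", "cat"))$n_correct, 2)
  # a repeated keyword needs a repeated response token
  expect_equal(score_keywords(c("a"), c("a", "a"))$n_correct, 1)
  expect_error(score_keywords("a", character(0)), "non-empty")
})

test_that("RAU matches the closed form at the endpoints and is monotone", {
  expect_equal(rau(0, 33), -15.0, tolerance = 0.1)
  expect_equal(rau(33, 33), 115.0, tolerance = 0.1)
  expect_equal(rau(16, 32), 50, tolerance = 1.5)
  vals <- rau(0:33, 33)
  expect_true(all(diff(vals) > 0))
  expect_gt(min(vals), -23.01)
  expect_lt(max(vals), 123.01)
  expect_error(rau(5, 4), "n_correct")
})

test_that("Welch t matches an independent formula evaluation", {
  set.seed(3)
  for (i in 1:10) {
    a <- stats::rnorm(sample(5:20, 1), mean = stats::runif(1, -1, 1))
    b <- stats::rnorm(sample(5:20, 1), sd = stats::runif(1, 0.5, 2))
    got <- welch_t(a, b)
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_ref <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p_ref <- 2 * stats::pt(-abs(t_ref), df_ref)
    expect_equal(got$t, t_ref, tolerance = 1e-8)
    expect_equal(got$df, df_ref, tolerance = 1e-8)
    expect_equal(got$p, p_ref, tolerance = 1e-8)
  }
  # equal-variance equal-n limit: df = 2n - 2
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(welch_t(a, b)$df, 6)
  expect_lt(abs(welch_t(a, sample(a))$t), 1e-12)
  expect_error(welch_t(c(1, 1), c(1, 1)), "undefined")
})

test_that("rm-ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(42)
  d <- expand.grid(subject = paste0("S", 1:4), A = c("a1", "a2"),
                   B = c("b1", "b2", "b3"))
  d$percent <- round(50 + 8 * (d$A == "a2") +
                       c(0, 5, 12)[as.integer(factor(d$B))] +
                       stats::rnorm(nrow(d), 0, 4), 2)
  res <- rm_anova(d, dv = "percent", within = c("A", "B"),
                  subject = "subject")

  Y <- with(d, tapply(percent, list(subject, A, B), mean))
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  g <- mean(Y)
  ms <- apply(Y, 1, mean); mA <- apply(Y, 2, mean); mB <- apply(Y, 3, mean)
  msA <- apply(Y, c(1, 2), mean); msB <- apply(Y, c(1, 3), mean)
  mAB <- apply(Y, c(2, 3), mean)
  ss_subj <- a * b * sum((ms - g)^2)
  ssA <- n * b * sum((mA - g)^2)
  errA <- b * sum((msA - outer(ms, rep(1, a)) - outer(rep(1, n), mA) + g)^2)
  ssB <- n * a * sum((mB - g)^2)
  errB <- a * sum((msB - outer(ms, rep(1, b)) - outer(rep(1, n), mB) + g)^2)
  ssAB <- n * sum((mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + g)^2)
  resid <- Y
  for (s in 1:n) for (i in 1:a) for (j in 1:b)
    resid[s, i, j] <- Y[s, i, j] - msA[s, i] - msB[s, j] - mAB[i, j] +
      ms[s] + mA[i] + mB[j] - g
  errAB <- sum(resid^2)
  F_ref <- c(A = (ssA / (a - 1)) / (errA / ((a - 1) * (n - 1))),
             B = (ssB / (b - 1)) / (errB / ((b - 1) * (n - 1))),
             `A:B` = (ssAB / ((a - 1) * (b - 1))) /
               (errAB / ((a - 1) * (b - 1) * (n - 1))))
  den <- ss_subj + errA + errB + errAB
  ges_ref <- c(ssA, ssB, ssAB) / (c(ssA, ssB, ssAB) + den)

  expect_equal(res$F, unname(F_ref[res$effect]), tolerance = 1e-6)
  expect_equal(res$ges, unname(ges_ref), tolerance = 1e-6)

  # Greenhouse-Geisser epsilon against the double-centering formula
  YB <- apply(Y, c(1, 3), mean)
  S <- stats::cov(YB)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps_ref <- sum(diag(Sdc))^2 / ((b - 1) * sum(Sdc^2))
  expect_equal(res$epsilon[res$effect == "B"], eps_ref, tolerance = 1e-8)

  # Mauchly statistic against the stats implementation
  mt <- stats::mauchly.test(stats::lm(YB ~ 1), X = ~1)
  expect_equal(res$sphericity_W[res$effect == "B"],
               unname(mt$statistic), tolerance = 1e-8)
  expect_equal(res$sphericity_p[res$effect == "B"], mt$p.value,
               tolerance = 1e-8)
})

test_that("rm-ANOVA F values agree with aov error strata on the full design", {
  tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                            n_subjects = 8, keywords_per_condition = 33,
                            seed = 7)
  res <- rm_anova(tab)
  d <- tab
  for (col in c("subject", "silence_added", "spectral_content", "measurement"))
    d[[col]] <- factor(d[[col]])
  a <- stats::aov(percent ~ silence_added * spectral_content * measurement +
                    Error(subject / (silence_added * spectral_content *
                                       measurement)), data = d)
  sm <- summary(a)
  f_aov <- vapply(sm[-1], function(s) s[[1]][["F value"]][1], numeric(1))
  expect_equal(res$F, unname(f_aov), tolerance = 1e-6)
})

test_that("rm-ANOVA sphericity handling follows the two-level and GG rules", {
  tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                            n_subjects = 14, keywords_per_condition = 33,
                            seed = 9)
  res <- rm_anova(tab)
  two_level <- res[res$effect %in% c("silence_added", "measurement"), ]
  expect_true(all(two_level$epsilon == 1))
  expect_true(all(two_level$df_num == 1))

  multi <- res[grepl("spectral_content", res$effect), ]
  k_eff <- ifelse(multi$effect == "spectral_content", 3, NA)
  expect_true(all(multi$epsilon <= 1))
  expect_true(all(multi$epsilon >= 1 / 2))  # >= 1/(k-1) for d = 2
  # shrinking both dfs by epsilon <= 1 raises the p of any F that could be
  # declared significant (for F < 1 the inequality can flip; that region is
  # irrelevant to inference)
  big <- res$F >= 1
  expect_true(all(res$p[big] >= res$p_uncorrected[big] - 1e-12))
  corrected <- res[res$gg_applied, ]
  if (nrow(corrected))
    expect_true(all(corrected$df_num < 2))

  # F is invariant to adding a constant to all scores
  tab2 <- tab
  tab2$percent <- tab2$percent + 17
  expect_equal(rm_anova(tab2)$F, res$F, tolerance = 1e-10)
})

test_that("rm-ANOVA rejects incomplete designs", {
  tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                            n_subjects = 4, keywords_per_condition = 33,
                            seed = 2)
  expect_error(rm_anova(tab[-5, ]), "balanced")
})

test_that("Bonferroni post-hocs follow the multiplication rule", {
  tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                            n_subjects = 10, keywords_per_condition = 33,
                            seed = 3)
  ph <- posthoc_pairwise(tab, "spectral_content")
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p_adjusted <= 1))
  expect_equal(ph$p_adjusted, pmin(1, ph$p * 3))

  # identical paired values -> t = 0, adjusted p = 1
  flat <- data.frame(subject = rep(1:6, 2),
                     cond = rep(c("x", "y"), each = 6),
                     rau = rep(rau(10, 33), 12))
  ph0 <- posthoc_pairwise(flat, "cond")
  expect_equal(ph0$t, 0)
  expect_equal(ph0$p_adjusted, 1)   # single comparison: adjusted = raw
})

test_that("repackaging benefit is the silence minus no-silence contrast", {
  tab <- simulate_responses(psychometric_model(), main_experiment_design(),
                            n_subjects = 6, keywords_per_condition = 33,
                            seed = 4)
  b <- repackaging_benefit(tab)
  expect_equal(nrow(b), 6 * 3)
  one <- tab[tab$subject == "S01" & tab$spectral_content == "original", ]
  manual <- mean(one$percent[one$silence_added]) -
    mean(one$percent[!one$silence_added])
  expect_equal(b$benefit_percent[b$subject == "S01" &
                                   b$spectral_content == "original"], manual)
  # identical scores -> zero benefit
  flat <- tab
  flat$percent <- 40; flat$rau <- rau(13, 33)
  b0 <- repackaging_benefit(flat)
  expect_true(all(b0$benefit_percent == 0))
  expect_error(repackaging_benefit(tab[tab$silence_added, ]), "silence")
})

test_that("Shapiro-Wilk wrapper has nominal null behavior and power", {
  set.seed(8)
  p_null <- replicate(200, normality_check(stats::rnorm(50))$p)
  ks <- stats::ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)

  p_skew <- replicate(100, normality_check(stats::rexp(100))$p)
  expect_gte(mean(p_skew < 0.05), 0.9)

  res3 <- normality_check(c(1, 2, 3))
  expect_true(is.finite(res3$W))
  expect_error(normality_check(c(1, 1, 1)), "constant")
  expect_error(normality_check(c(1, 2)), "at least 3")
})
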