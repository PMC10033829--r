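test_that("scenario labels force the path-variance pattern", {
  expect_identical(sim_scenario("H00")$tau_alpha_sq, 0)
  expect_identical(sim_scenario("H00")$tau_beta_sq, 0)
  expect_gt(sim_scenario("H01")$tau_beta_sq, 0)
  expect_identical(sim_scenario("H01")$tau_alpha_sq, 0)
  expect_error(sim_scenario("H00", tau_alpha_sq = 0.2), "inconsistent")
  expect_error(sim_scenario("H11", tau_beta_sq = 0), "inconsistent")
  expect_error(sim_scenario("H11", rho = 1), "rho")
  expect_error(simulate_cohort(5), ">= 10")
  expect_error(cohort_config(cell_conc = c(a = -1, b = 1, c = 1, d = 1,
                                           e = 1, f = 1)), "positive")
})

test_that("the cohort draw is deterministic, confounded, and prevalence-calibrated", {
  ph1 <- simulate_cohort(352, seed = 20)
  ph2 <- simulate_cohort(352, seed = 20)
  expect_identical(ph1, ph2)
  # realized prevalence within the binomial 95% CI of the 43.7% target
  prev <- mean(ph1$exposure)
  half <- 1.96 * sqrt(0.437 * (1 - 0.437) / 352)
  expect_lt(abs(prev - 0.437), half)
  # cell proportions live in [0, 1] and leave room for granulocytes
  cells <- as.matrix(ph1[, c("CD4T", "CD8T", "Bcell", "NK", "Mono")])
  expect_true(all(cells >= 0 & cells <= 1))
  expect_true(all(rowSums(cells) < 1))
  # zero coefficients and zero intercept give prevalence ~ 1/2
  cfg <- cohort_config(exposure_intercept = 0,
                       exposure_coef = c(age = 0, sex = 0, bmi = 0))
  ph0 <- simulate_cohort(20000, cfg, seed = 21)
  expect_lt(abs(mean(ph0$exposure) - 0.5), 0.01)
})

test_that("the exchangeable residual block attains the target correlation", {
  ph <- simulate_cohort(352, seed = 30)
  offdiag <- numeric(1000)
  for (i in seq_len(1000)) {
    sc <- sim_scenario("H00", n = 352, K = 16, rho = 0.9,
                       covar_effect_sd = 0, seed = 30000 + i)
    E <- simulate_gene(sc, ph)$M
    cr <- cor(E)
    offdiag[i] <- mean(cr[upper.tri(cr)])
  }
  expect_lt(abs(mean(offdiag) - 0.9), 0.02)
})

test_that("AR(1) residuals decay with lag and sparse effects zero a fraction", {
  ph <- simulate_cohort(352, seed = 35)
  lag1 <- lag5 <- numeric(200)
  for (i in seq_len(200)) {
    sc <- sim_scenario("H00", n = 352, K = 8, rho = 0.7, corstr = "ar1",
                       covar_effect_sd = 0, seed = 36000 + i)
    cr <- cor(simulate_gene(sc, ph)$M)
    lag1[i] <- mean(cr[row(cr) == col(cr) + 1])
    lag5[i] <- mean(cr[row(cr) == col(cr) + 5])
  }
  expect_lt(abs(mean(lag1) - 0.7), 0.03)
  expect_lt(abs(mean(lag5) - 0.7^5), 0.03)
  # sparse variant: about half the alpha draws are exactly zero
  zeros <- vapply(1:100, function(i) {
    sc <- sim_scenario("H10", n = 352, K = 20, sparsity_alpha = 0.5,
                       seed = 37000 + i)
    sum(simulate_gene(sc, ph)$alpha == 0)
  }, 0)
  expect_lt(abs(mean(zeros) / 20 - 0.5), 0.05)
})

test_that("per-CpG regression recovers the drawn exposure effects", {
  ph <- simulate_cohort(2000, seed = 40)
  sc <- sim_scenario("H10", n = 2000, K = 10, tau_alpha_sq = 0.25,
                     rho = 0, covar_effect_sd = 0, seed = 41)
  sim <- simulate_gene(sc, ph)
  X <- ph$exposure
  slopes <- vapply(seq_len(10), function(k)
    coef(lm.fit(cbind(1, X), sim$M[, k]))[2L], 0)
  rmse <- sqrt(mean((slopes - sim$alpha)^2))
  # OLS sampling bound: 2 * sigma_m / sqrt(n * var share of X)
  expect_lt(rmse, 2 * sqrt(sc$sigma_m_sq) / sqrt(2000 * var(X)))
})

test_that("H00 genes carry no exposure signal at any CpG", {
  ph <- simulate_cohort(300, seed = 50)
  X <- ph$exposure
  ps <- numeric(2000)
  j <- 1L
  for (i in seq_len(125)) {
    sc <- sim_scenario("H00", n = 300, K = 16, covar_effect_sd = 0,
                       seed = 50000 + i)
    M <- simulate_gene(sc, ph)$M
    for (k in seq_len(16)) {
      ps[j] <- t.test(M[X == 1, k], M[X == 0, k])$p.value
      j <- j + 1L
    }
  }
  expect_gt(suppressWarnings(ks.test(ps[seq_len(2000)], "punif"))$p.value, 0.01)
})

test_that("study assembly respects the mix, the truth table and determinism", {
  base <- sim_scenario("H11", n = 60, K = 4)
  st1 <- simulate_study(200, c(H00 = 1), base, seed = 60)
  expect_true(all(st1$truth$label == "H00"))
  expect_true(all(abs(st1$truth$alpha_sum) == 0))
  expect_true(all(abs(st1$truth$beta_sum) == 0))
  st2 <- simulate_study(200, c(H00 = 1), base, seed = 60)
  expect_identical(st1, st2)

  # multinomial label counts inside the 99% CI at G = 5000
  mix <- c(H00 = 0.8, H01 = 0.1, H10 = 0.1)
  st3 <- simulate_study(5000, mix, sim_scenario("H11", n = 20, K = 2),
                        seed = 61)
  counts <- table(factor(st3$truth$label, levels = names(mix)))
  for (l in names(mix)) {
    p <- mix[[l]]
    half <- 2.576 * sqrt(p * (1 - p) * 5000)
    expect_lt(abs(counts[[l]] - 5000 * p), half)
  }
  expect_error(simulate_study(10, c(H00 = 0.6, H01 = 0.3), base), "sum to 1")
  expect_error(simulate_study(10, c(H99 = 1), base), "labels")
})

test_that("a noise-only gaussian outcome has unit variance", {
  base <- sim_scenario("H00", n = 352, K = 4, sigma_y_sq = 1,
                       covar_effect_sd = 0)
  st <- simulate_study(5, c(H00 = 1), base, seed = 70,
                       y_covar_coef = c(age = 0, sex = 0, bmi = 0))
  expect_lt(abs(var(st$phenotypes$outcome) - 1), 0.1)
})

test_that("isolated outcomes carry exactly one gene's contribution", {
  base <- sim_scenario("H11", n = 500, K = 4, tau_beta_sq = 0.5)
  st <- simulate_study(20, c(H00 = 0.5, H11 = 0.5), base, seed = 80,
                       isolated = TRUE)
  expect_identical(dim(st$outcomes_isolated), c(500L, 20L))
  h11 <- which(st$truth$label == "H11")[1L]
  h00 <- which(st$truth$label == "H00")[1L]
  probes_of <- function(g) match(st$gene_map$probes[[g]], st$methylation$probe_ids)
  M11 <- t(st$methylation$values[probes_of(h11), ])
  # the H11 gene's own outcome correlates with M beta; an H00 gene's does not
  expect_gt(abs(cor(st$outcomes_isolated[, h11],
                    M11 %*% st$truth$beta[[h11]])), 0.3)
  expect_equal(sum(abs(st$truth$beta[[h00]])), 0)
})
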