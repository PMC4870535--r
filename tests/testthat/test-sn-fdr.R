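test_that("system S/N is the ratio of mean cross-state to mean intra-replicate sds", {
  set.seed(40)
  pops <- make_pops(Z0 = rnorm(500, 0, 5), Z1 = rnorm(500, 0, 5),
                    R0 = rnorm(500, 0, 1), R1 = rnorm(500, 0, 1))
  expect_equal(system_sn(pops),
               mean(c(sd(pops$Z0), sd(pops$Z1))) /
                 mean(c(sd(pops$R0), sd(pops$R1))))
  expect_equal(system_sn(pops), 5, tolerance = 0.2)
  same <- make_pops(Z0 = pops$R0, Z1 = pops$R1,
                    R0 = pops$R0, R1 = pops$R1)
  expect_equal(system_sn(same), 1.0)
  degenerate <- make_pops(Z0 = rnorm(5), Z1 = rnorm(5),
                          R0 = rep(0, 5), R1 = rep(0, 5))
  expect_error(system_sn(degenerate), "degenerate")
})

test_that("per-protein S/N is the normalized vector-magnitude ratio", {
  set.seed(41)
  # bulk keeps each population near mean 0 / sd 1 so normalization is ~identity
  n <- 20000
  pops <- make_pops(Z0 = c(3, 0, rnorm(n)), Z1 = c(3, 0, rnorm(n)),
                    R0 = c(1, 1, rnorm(n)), R1 = c(1, 1, rnorm(n)))
  sn <- protein_sn(pops)
  expect_equal(unname(sn[1]), 3, tolerance = 0.02)  # sqrt(18)/sqrt(2)
  expect_equal(unname(sn[2]), 0, tolerance = 0.02)
  expect_true(all(sn >= 0))
})

test_that("zero intra-replicate magnitude gives a flagged infinite S/N that passes the filter", {
  set.seed(42)
  m <- matrix(2^rnorm(80, 20, 2), 20, 4,
              dimnames = list(sprintf("p%02d", 1:20),
                              c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  # protein 1: perfect replicate agreement within both states, clear effect
  m[1, ] <- c(4096, 4096, 1024, 1024)
  tab <- tic_table(m, c("A", "A", "B", "B"), c(1, 2, 1, 2))
  fit <- znet(tab)
  sn <- protein_sn(fit$pops)
  expect_true(is.infinite(sn[["p01"]]))
  expect_identical(attr(sn, "infinite_sn"), "p01")
  expect_warning(fit2 <- apply_sn_filter(fit, 2.8), "infinite")
  expect_true(fit2$table$fdr_reliable[fit2$table$protein_id == "p01"])
})

test_that("the S/N filter is strict at the cutoff and matches a brute-force scan", {
  fit <- znet(random_tic_table(10, seed = 44))
  fit$table$sn <- c(2.8, 5, 0.1, 2.81, 3.5, 1, 2.79, 0.5, 10, 2.8)
  fit <- apply_sn_filter(fit, 2.8)
  manual <- logical(10)
  for (i in 1:10) manual[i] <- fit$table$sn[i] > 2.8
  expect_identical(fit$table$fdr_reliable, manual)
  expect_equal(sum(fit$table$fdr_reliable), 4)
  expect_false(fit$table$fdr_reliable[1])  # sn == 2.8 exactly: not passing
})

test_that("null S/N survival follows the F(2,2) closed form on independent populations", {
  set.seed(45)
  n <- 100000
  pops <- make_pops(Z0 = rnorm(n), Z1 = rnorm(n),
                    R0 = rnorm(n), R1 = rnorm(n))
  sn <- protein_sn(pops)
  for (cutoff in c(1, 2, 2.8, 4)) {
    expect_lt(abs(mean(sn > cutoff) - 1 / (1 + cutoff^2)), 0.01)
  }
  # identical to pf() of the squared statistic, the textbook route
  expect_lt(abs(mean(sn^2 > 2.8^2) -
                  stats::pf(2.8^2, 2, 2, lower.tail = FALSE)), 0.01)
})

test_that("the raw-scale S/N variant agrees with the normalized one under equal sds", {
  set.seed(46)
  n <- 5000
  pops <- make_pops(Z0 = rnorm(n, 0, 3), Z1 = rnorm(n, 0, 3),
                    R0 = rnorm(n, 0, 1), R1 = rnorm(n, 0, 1))
  a <- protein_sn(pops, scale = "normalized")
  b <- protein_sn(pops, scale = "raw")
  # populations are centered with matching sds, so the two scalings differ
  # only through sampling noise in the population moments
  expect_equal(stats::cor(log(a + 1e-6), log(b + 1e-6)), 1, tolerance = 0.01)
  expect_equal(unname(stats::quantile(a / b, c(0.05, 0.95))), c(1, 1),
               tolerance = 0.1)
})

test_that("Monte-Carlo FDR is ~1 on pure-null data and nonincreasing in the cutoff", {
  sim <- simulate_tic_experiment(sim_config(
    n_proteins = 2000, de_fraction = 0, effect_log2 = 0, seed = 47))
  fit <- znet(sim$table)
  curve <- monte_carlo_fdr(fit, reps = 150, seed = 48)
  ok <- !is.na(curve$fdr)
  expect_true(all(diff(curve$fdr[ok]) <= 0))
  expect_true(all(curve$fdr[ok] >= 0 & curve$fdr[ok] <= 1))
  # everything is null: estimated FDR stays near 1 wherever discoveries exist
  busy <- ok & curve$n_obs >= 50
  expect_true(all(curve$fdr[busy] > 0.8))
})

test_that("Monte-Carlo FDR requires a seed and enough reps, NA where no discoveries", {
  fit <- znet(random_tic_table(50, seed = 50))
  expect_error(monte_carlo_fdr(fit, reps = 100), "seed")
  expect_error(monte_carlo_fdr(fit, reps = 10, seed = 1), "reps")
  curve <- monte_carlo_fdr(fit, cutoffs = c(0, 1, 1e6), reps = 100, seed = 2)
  expect_true(is.na(curve$fdr[curve$cutoff == 1e6]))  # no obs above 1e6
  expect_error(monte_carlo_fdr(fit, cutoffs = c(2, 1), reps = 100, seed = 2),
               "ascending")
})

test_that("Monte-Carlo FDR agrees with truth-label FDR on the paperlike preset", {
  sim <- simulate_tic_experiment(sim_config(preset = "paperlike", seed = 51))
  fit <- znet(sim$table)
  tab <- merge(fit$table, sim$truth, by = "protein_id")
  called <- tab$sn > 2.8
  truth_fdr <- mean(tab$label[called] == "null")
  curve <- monte_carlo_fdr(fit, reps = 300, seed = 52)
  expect_lte(abs(fdr_at(curve, 2.8) - truth_fdr), 0.05)
  expect_lte(truth_fdr, 0.10)
  expect_lte(fdr_at(curve, 2.8), 0.10)
})

test_that("estimated FDR at 2.8 does not increase when the true effect grows", {
  fdr_for_effect <- function(effect) {
    sim <- simulate_tic_experiment(sim_config(
      n_proteins = 3000, de_fraction = 0.2, effect_log2 = effect,
      rep_noise_sd = 0.4, seed = 53))
    fdr_at(monte_carlo_fdr(znet(sim$table), reps = 150, seed = 54), 2.8)
  }
  fdrs <- vapply(c(3, 5, 8), fdr_for_effect, numeric(1))
  expect_true(all(diff(fdrs) <= 0.02))  # matched seeds, small MC slack
})

test_that("permutation nulls preserve each protein's four values", {
  sim <- simulate_tic_experiment(sim_config(n_proteins = 30, seed = 55))
  fit <- znet(sim$table)
  nulls <- simulate(fit, nsim = 3, seed = 56)
  expect_length(nulls, 3)
  for (nl in nulls) {
    # the multiset of log2 values per protein is untouched by relabeling
    expect_equal(t(apply(nl$log2_tic, 1, sort)),
                 t(apply(fit$pops$log2_tic, 1, sort)))
    # but the state partition always differs: Z pairs mix original states
    expect_false(all(nl$Z0 == fit$pops$Z0))
  }
})
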