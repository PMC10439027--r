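test_that("th75 equals the fitted location parameter and inversion matches a grid oracle", {
  levels <- seq(30, 70, 5)
  trials <- data.frame(sigma = rep(levels, each = 150))
  model <- observer_model(mu_true = 50, slope_true = 10, seed = 61)
  trials$condition <- "cued"
  resp <- simulate_responses(trials, model)
  fit <- fit_cumulative_gaussian(resp, "sigma")
  expect_true(fit$converged)
  expect_identical(fit$th75, fit$mu)
  expect_equal(threshold_at(fit, 0.75), fit$mu)
  # criterion 0.5 + 0.5 * pnorm(1) lies one spread from mu (decreasing: below)
  expect_equal(threshold_at(fit, 0.5 + 0.5 * stats::pnorm(1)),
               fit$mu - fit$slope_sd, tolerance = 1e-9)
  # dense numerical inversion of the fitted curve agrees
  for (crit in c(0.6, 0.75, 0.9)) {
    xs <- seq(fit$mu - 8 * fit$slope_sd, fit$mu + 8 * fit$slope_sd, length.out = 2e5)
    ys <- predict_accuracy(fit, xs)
    oracle <- suppressWarnings(stats::approx(ys, xs, xout = crit)$y)
    expect_equal(threshold_at(fit, crit), oracle, tolerance = 1e-4)
  }
  expect_error(threshold_at(fit, 0.4), "criterion")
  expect_error(threshold_at(fit, 1), "criterion")
})

test_that("parameters are recovered without bias and with shrinking error", {
  levels <- seq(30, 70, 5)
  run_fits <- function(n_per_level, n_rep, seed0) {
    vapply(seq_len(n_rep), function(r) {
      trials <- data.frame(sigma = rep(levels, each = n_per_level),
                           condition = "cued")
      resp <- simulate_responses(trials, observer_model(50, 10, seed = seed0 + r))
      fit_cumulative_gaussian(resp, "sigma")$mu
    }, numeric(1))
  }
  mus <- run_fits(200, 120, seed0 = 1000)
  expect_lt(abs(mean(mus) - 50), 1)
  expect_lt(sqrt(mean((mus - 50)^2)), 2)
  # recovery error shrinks as trials grow
  rmse <- vapply(c(25, 100, 400), function(n) {
    sqrt(mean((run_fits(n, 40, seed0 = 3000 + n) - 50)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("fit likelihood at the optimum dominates the generating parameters", {
  levels <- seq(30, 70, 5)
  trials <- data.frame(sigma = rep(levels, each = 60), condition = "cued")
  resp <- simulate_responses(trials, observer_model(50, 10, seed = 62))
  fit <- fit_cumulative_gaussian(resp, "sigma")
  loglik_at <- function(mu, sd) {
    p <- 0.5 + 0.5 * stats::pnorm(-(resp$sigma - mu) / sd)
    sum(resp$correct * log(p) + (1 - resp$correct) * log(1 - p))
  }
  expect_gte(fit$loglik + 1e-6, loglik_at(50, 10))
})

test_that("degenerate response patterns are flagged, never silently estimated", {
  levels <- seq(30, 70, 5)
  chance <- data.frame(sigma = rep(levels, 30))
  chance$correct <- with_seed(63, stats::rbinom(nrow(chance), 1, 0.5))
  fc <- fit_cumulative_gaussian(chance, "sigma")
  expect_false(fc$converged)
  expect_match(fc$note, "outside the tested|parameter bound")
  expect_error(threshold_at(fc), "non-converged")
  perfect <- data.frame(sigma = rep(levels, 5), correct = 1)
  fp <- fit_cumulative_gaussian(perfect, "sigma")
  expect_false(fp$converged)
  expect_error(fit_cumulative_gaussian(data.frame(sigma = 30, correct = 1), "sigma"),
               "2 distinct")
})

test_that("permutation p-values honour the +1 convention and Bonferroni arithmetic", {
  tab <- null_pair_table(n_obs = 20, n_per = 8, seed = 64)
  # inject a massive condition effect: the observed difference should beat
  # (almost surely) every resample, pinning p at the +1 boundary
  tab$correct <- tab$correct + ifelse(tab$condition == "a", 10, 0)
  res <- permutation_test(tab, iterations = 500, seed = 65, n_comparisons = 3)
  expect_equal(res$p_raw, 1 / 501)
  expect_equal(res$p_bonferroni, 3 / 501)
  raw <- permutation_test(tab, iterations = 500, seed = 65, plus_one = FALSE)
  expect_equal(raw$p_raw, 0)
  # Bonferroni caps at 1
  null_tab <- null_pair_table(seed = 66)
  r2 <- permutation_test(null_tab, iterations = 200, seed = 67, n_comparisons = 50)
  expect_equal(r2$p_bonferroni, min(1, 50 * r2$p_raw))
  expect_true(r2$p_raw >= 0 && r2$p_raw <= 1)
})

test_that("permutation test is two-sided: invariant to swapping group labels", {
  tab <- null_pair_table(seed = 68)
  tab$correct <- tab$correct + ifelse(tab$condition == "a", 0.05, 0)
  p1 <- permutation_test(tab, iterations = 400, seed = 69)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "a", "b", "a")
  p2 <- permutation_test(swapped, iterations = 400, seed = 69)
  expect_equal(p1$p_raw, p2$p_raw)
  expect_equal(p1$observed_diff, -p2$observed_diff)
})

test_that("permutation test validates its grouping structure", {
  tab <- null_pair_table(seed = 70)
  expect_error(permutation_test(tab[tab$condition == "a", ]), "exactly 2 levels")
  three <- rbind(tab, transform(tab[1:10, ], condition = "c"))
  expect_error(permutation_test(three), "exactly 2 levels")
  unpaired <- tab[!(tab$observer == 1 & tab$condition == "b"), ]
  expect_error(permutation_test(unpaired), "both groups")
})

test_that("location summaries aggregate correctly and interpolate linearly", {
  tab <- data.frame(observer = "o1",
                    position = rep(c(0, 4), each = 10),
                    correct = rep(c(0.6, 0.8), each = 10))
  s <- summarize_by_location(tab)
  expect_equal(s$summary$mean, c(0.6, 0.8))
  expect_equal(s$interpolate(2), 0.7)
  # SEM of identical observers is zero
  tab2 <- rbind(tab, transform(tab, observer = "o2"))
  s2 <- summarize_by_location(tab2)
  expect_equal(s2$summary$sem, c(0, 0))
  # independent group-by oracle on richer data
  tab3 <- data.frame(
    observer = rep(sprintf("o%d", 1:5), each = 40),
    position = rep(rep(c(-4, 0, 4, 8), each = 10), 5))
  tab3$correct <- with_seed(71, stats::rbinom(nrow(tab3), 1, 0.7))
  s3 <- summarize_by_location(tab3)
  oracle <- sapply(c(-4, 0, 4, 8), function(p) {
    per_obs <- sapply(sprintf("o%d", 1:5), function(o) {
      mean(tab3$correct[tab3$observer == o & tab3$position == p])
    })
    mean(per_obs)
  })
  expect_equal(s3$summary$mean, oracle)
})

test_that("response tables round-trip through CSV", {
  tab <- data.frame(observer = "s1", condition = "cued", sigma = c(30, 50),
                    correct = c(1L, 0L))
  path <- tempfile(fileext = ".csv")
  write_response_table(tab, path)
  back <- read_response_table(path)
  expect_equal(back, tab)
  expect_error(read_response_table(tempfile()), "no such file")
})
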