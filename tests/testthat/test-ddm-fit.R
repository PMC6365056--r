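test_that("observed quantile bins hold the forced proportions", {
  set.seed(3)
  rt <- runif(100, 0.25, 0.8)
  choice <- c(rep("press", 100), rep("none", 20))
  ob <- observed_bins(choice, c(rt, rep(NA, 20)))
  expect_equal(ob$counts, c(10, 20, 20, 20, 20, 10, 20))
  expect_equal(ob$n, 120)
  expect_false(ob$collapsed)
})

test_that("sub-cutoff presses are discarded before binning", {
  rt <- c(runif(50, 0.25, 0.8), runif(5, 0.05, 0.15))
  choice <- c(rep("press", 55), rep("none", 10))
  ob <- observed_bins(choice, c(rt, rep(NA, 10)))
  expect_equal(ob$n_press, 50)
  expect_equal(sum(ob$counts), 60)
})

test_that("bin counts are invariant to trial order, ties included", {
  # 10-trial toy with tied RTs, exhaustively reshuffled
  rt <- c(0.3, 0.3, 0.4, 0.4, 0.4, 0.5, 0.6, 0.6, 0.7, 0.8)
  choice <- rep("press", 10)
  ref <- observed_bins(choice, rt)
  set.seed(1)
  for (i in 1:25) {
    o <- sample(10)
    ob <- observed_bins(choice[o], rt[o])
    expect_identical(ob$counts, ref$counts)
    expect_identical(ob$q, ref$q)
  }
})

test_that("sparse and empty press cells collapse with a flag", {
  ob <- observed_bins(c(rep("press", 5), rep("none", 20)),
                      c(runif(5, 0.3, 0.6), rep(NA, 20)))
  expect_true(ob$collapsed)
  expect_equal(length(ob$counts), 3)
  ob2 <- observed_bins(rep("none", 15), rep(NA_real_, 15))
  expect_true(ob2$degenerate)
  expect_equal(ob2$counts, c(0L, 15L))
})

test_that("expected bin probabilities are a proper distribution", {
  set.seed(7)
  for (i in 1:10) {
    p <- ddm_params(v = runif(1, -3, 3), a = runif(1, 0.5, 2),
                    z_frac = runif(1, 0.2, 0.8), db = runif(1, -2, 2),
                    t_nd = runif(1, 0.1, 0.4))
    q <- sort(runif(5, 0.25, 0.8))
    e <- expected_bins(p, sample(c("target", "nontarget"), 1), q)
    expect_equal(sum(e), 1, tolerance = 1e-9)
    expect_true(all(e >= 0))
  }
})

test_that("expected bins match Monte-Carlo frequencies from the simulator", {
  p <- ddm_params(v = 2, a = 1, z_frac = 0.3, db = 0.8, t_nd = 0.3)
  n <- 40000
  sim <- ddm_simulate(p, "target", n, dt = 1e-4, deadline = 0.84, seed = 2)
  ob <- observed_bins(sim$choice, sim$rt)
  e <- expected_bins(p, "target", ob$q)
  obs_frac <- ob$counts / ob$n
  se <- sqrt(e * (1 - e) / ob$n)
  expect_true(all(abs(obs_frac - e) < 3 * se + 0.01))
})

test_that("an overwhelming drift bias drives the no-response mass to zero", {
  p <- ddm_params(v = 1, a = 1, z_frac = 0.5, db = 40, t_nd = 0.25)
  e <- expected_bins(p, "nontarget", c(0.3, 0.35, 0.4, 0.45, 0.5))
  expect_lt(e[length(e)], 1e-4)
})

test_that("G-square follows the multinomial deviance definition", {
  expect_equal(gsquare(c(60, 40), c(0.5, 0.5)),
               4.027102710137775, tolerance = 1e-12)
  expect_equal(gsquare(c(30, 60, 10), c(0.3, 0.6, 0.1)), 0)
  expect_equal(gsquare(c(0, 5, 5), c(0.2, 0.4, 0.4)),
               2 * (5 * log(5 / 4) + 5 * log(5 / 4)))
  # equals twice the log-likelihood ratio against the saturated multinomial
  o <- c(12, 3, 25); p <- c(0.3, 0.2, 0.5); n <- sum(o)
  ll <- function(pr) sum(o * log(pr))
  expect_equal(gsquare(o, p), 2 * (ll(o / n) - ll(p)), tolerance = 1e-12)
  expect_true(is.infinite(gsquare(c(1, 1), c(0, 1))))
})

test_that("model variants free the advertised parameters", {
  expect_equal(sort(ddm_model_spec("fixed")$shared),
               c("db", "z_frac"))
  expect_equal(ddm_model_spec("drift_bias")$shared, "z_frac")
  expect_equal(ddm_model_spec("starting_point")$shared, "db")
  # parameter counts: 3 per condition x 2 + shared
  expect_equal(length(driftgain:::.ddm_layout(ddm_model_spec("fixed"),
                                              c("a", "b"))), 8)
  expect_equal(length(driftgain:::.ddm_layout(ddm_model_spec("drift_bias"),
                                              c("a", "b"))), 9)
})

test_that("fits are deterministic and the reported G2 re-evaluates", {
  tr <- sim_two_condition(900, n_lib = c(540L, 180L), n_con = c(540L, 180L))
  f1 <- ddm_fit(tr, "drift_bias", restarts = 2, seed = 3)
  f2 <- ddm_fit(tr, "drift_bias", restarts = 2, seed = 3)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$g2, f2$g2)
  # re-evaluate the winning parameters by hand
  g2 <- 0
  for (cond in names(f1$params)) for (stim in c("target", "nontarget")) {
    idx <- tr$condition == cond & tr$stimulus == stim
    ob <- observed_bins(tr$choice[idx], tr$rt[idx])
    pr <- expected_bins(f1$params[[cond]], stim, ob$q)
    g2 <- g2 + gsquare(ob$counts, pr, ob$n)
  }
  expect_equal(g2, f1$g2, tolerance = 1e-10)
})

test_that("BIC ranking reduces to G2 for equal parameter counts", {
  tr <- sim_two_condition(901, n_lib = c(540L, 180L), n_con = c(540L, 180L))
  fd <- ddm_fit(tr, "drift_bias", restarts = 2, seed = 1)
  fs <- ddm_fit(tr, "starting_point", restarts = 2, seed = 1)
  cmp <- compare_models(list(fd, fs))
  expect_equal(fd$n_free, fs$n_free)
  expect_equal(abs(diff(cmp$bic)), abs(fd$g2 - fs$g2), tolerance = 1e-9)
  fs2 <- fs; fs2$n_trials <- fs$n_trials - 1
  expect_error(compare_models(list(fd, fs2)), "same trials")
})
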