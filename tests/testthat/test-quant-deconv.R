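test_that("the tabulated peak-height column gives beta_hat = 0.295", {
  db <- table1_db()
  tab <- table2()
  m <- two_contributor_model(db$profiles[c(H22, H23)],
                             sites = tab$sites, rcrs_row = TRUE)
  fit <- fit_mixture(tab$y1, m)
  # closed form on the printed column: informative deviations at
  # 16189, 16224, 16293, 16311 average (0.30 + 0.32 + 0.29 + 0.27)/4
  expect_equal(fit$beta_hat, 0.295, tolerance = 1e-12)
  expect_equal(fit$n_sites, 11)
})

test_that("closed form agrees with the generic least-squares solver", {
  set.seed(23)
  pool <- c(16069, 16093, 16126, 16189, 16224, 16293, 16311)
  done <- 0
  while (done < 30) {
    p1 <- random_profile(pool); p2 <- random_profile(pool)
    if (same_profile(p1, p2)) next
    m <- two_contributor_model(list(p1, p2), sites = pool)
    if (sum((m$x1 - m$x2)^2) == 0) next
    y <- runif(length(pool))
    names(y) <- m$sites
    fit <- fit_mixture(y, m)
    lmfit <- lm(I(y - m$x2) ~ 0 + I(m$x1 - m$x2))
    expect_equal(fit$beta_hat, unname(coef(lmfit)), tolerance = 1e-10)
    expect_equal(fit$se, sqrt(diag(vcov(lmfit)))[[1]], tolerance = 1e-10)
    expect_equal(fit$p_value_beta0,
                 summary(lmfit)$coefficients[1, 4], tolerance = 1e-10)
    done <- done + 1
  }
})

test_that("noise-free mixtures are recovered exactly and symmetrically", {
  db <- table1_db()
  tab <- table2()
  pair <- db$profiles[c(H22, H23)]
  m12 <- two_contributor_model(pair, sites = tab$sites, rcrs_row = TRUE)
  y <- 0.3 * m12$x1 + 0.7 * m12$x2
  names(y) <- m12$sites
  fit <- fit_mixture(y, m12)
  expect_equal(fit$beta_hat, 0.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # swapping the pair order flips the fraction
  m21 <- two_contributor_model(rev(pair), sites = tab$sites,
                               rcrs_row = TRUE)
  fit21 <- fit_mixture(y, m21)
  expect_equal(fit21$beta_hat, 1 - fit$beta_hat, tolerance = 1e-12)
  expect_equal(fit21$r_squared, fit$r_squared, tolerance = 1e-12)
})

test_that("degenerate and flagged fits are reported, not hidden", {
  p <- parse_profile("16093 16189")
  expect_error(fit_mixture(c(a = 0.5), two_contributor_model(list(p, p),
                                                             sites = 16093)),
               "unidentifiable")
  # constant response with a non-constant design is flagged
  m <- two_contributor_model(list(parse_profile("16093"),
                                  parse_profile("rCRS")),
                             sites = c(16093, 16189))
  fit <- fit_mixture(c(`16093` = 0.4, `16189` = 0.4), m)
  expect_true("constant_response" %in% fit$flags)
  # out-of-range estimates are flagged, never clamped
  fit2 <- fit_mixture(c(`16093` = 1.4, `16189` = 0), m)
  expect_gt(fit2$beta_hat, 1)
  expect_true("beta_out_of_range" %in% fit2$flags)
})

test_that("the true pair fits the tabulated column better", {
  db <- table1_db()
  tab <- table2()
  r2_true <- model_fit(tab$y1,
                       two_contributor_model(db$profiles[c(H22, H23)],
                                             sites = tab$sites,
                                             rcrs_row = TRUE))
  r2_false <- model_fit(tab$y1,
                        two_contributor_model(db$profiles[c(H1263, H2135)],
                                              sites = tab$sites,
                                              rcrs_row = TRUE))
  expect_gt(r2_true, r2_false)
})

test_that("rank_hypotheses orders by fit and flags ties", {
  db <- table1_db()
  tab <- table2()
  rk <- rank_hypotheses(tab$y1,
                        list(db$profiles[c(H1263, H2135)],
                             db$profiles[c(H22, H23)]),
                        sites = tab$sites, rcrs_row = TRUE)
  expect_equal(rk$order, c(2L, 1L))
  expect_false(rk$tied)
  # both orderings of one unordered pair fit identically, hence tie
  rk2 <- rank_hypotheses(tab$y1,
                         list(db$profiles[c(H22, H23)],
                              db$profiles[c(H23, H22)]),
                         sites = tab$sites, rcrs_row = TRUE)
  expect_true(rk2$tied)
  expect_equal(rk2$fits[[1]]$r_squared, rk2$fits[[2]]$r_squared)
  expect_error(rank_hypotheses(tab$y1, list()), "no candidate")
  single <- rank_hypotheses(tab$y1, list(db$profiles[c(H22, H23)]),
                            sites = tab$sites, rcrs_row = TRUE)
  expect_length(single$fits, 1)
})

test_that("no-contribution test: exact null gives t = 0, p = 1", {
  db <- table1_db()
  tab <- table2()
  m <- two_contributor_model(db$profiles[c(H22, H23)], sites = tab$sites,
                             rcrs_row = TRUE)
  y <- m$x2
  names(y) <- m$sites
  expect_equal(test_no_contribution(y, m, contributor = 1), 1)
  expect_equal(fit_mixture(y, m)$beta_hat, 0)
  # and the mirrored null for contributor 2
  y1 <- m$x1
  names(y1) <- m$sites
  expect_equal(test_no_contribution(y1, m, contributor = 2), 1)
})

test_that("no-contribution test has power at beta = 0.3, sigma = 0.02", {
  db <- table1_db()
  tab <- table2()
  m <- two_contributor_model(db$profiles[c(H22, H23)], sites = tab$sites,
                             rcrs_row = TRUE)
  set.seed(29)
  reject <- replicate(1000, {
    obs <- simulate_peaks(m, beta = 0.3, sigma = 0.02)
    fit_mixture(obs$peaks, m)$p_value_beta0 < 0.05
  })
  expect_gt(mean(reject), 0.99)
})

test_that("p-values are approximately uniform under a true null", {
  db <- table1_db()
  tab <- table2()
  m <- two_contributor_model(db$profiles[c(H22, H23)], sites = tab$sites,
                             rcrs_row = TRUE)
  set.seed(31)
  n <- 2000
  # beta = 0 (pure contributor 2); unbounded errors so the t-test's
  # normality assumption holds exactly
  rej <- replicate(n, {
    obs <- simulate_peaks(m, beta = 0, sigma = 0.05, truncation = "none")
    fit_mixture(obs$peaks, m)$p_value_beta0 < 0.05
  })
  bound <- qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(rej) - 0.05), bound)
})

test_that("mixture_fit behaves like a standard fitted-model object", {
  db <- table1_db()
  tab <- table2()
  m <- two_contributor_model(db$profiles[c(H22, H23)], sites = tab$sites,
                             rcrs_row = TRUE)
  fit <- fit_mixture(tab$y1, m)
  expect_named(coef(fit), "beta")
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(fit$y))
  expect_equal(predict(fit), fit$fitted_values)
  ci <- confint(fit)
  expect_lt(ci[1, 1], fit$beta_hat)
  expect_gt(ci[1, 2], fit$beta_hat)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(11L, 3L))
  expect_true(all(sims >= 0 & sims <= 1))
  expect_output(print(summary(fit)), "contributor 1 absent")
})
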