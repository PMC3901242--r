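test_that("global residuals are the weighted model-minus-observed vector", {
  dat <- pgi_grid_dataset()
  prob <- global_fit_problem("pgi", dat, free = PGI_TRUTH, fixed = c(h = 1),
                             seed = 1)
  # residuals at the generating parameters vanish (self-consistency)
  r <- residuals_global(PGI_TRUTH, prob)
  expect_length(r, nrow(dat))
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(dat$rate^2)), 1e-12)
  # Vf -> 0: residuals are the observed rates negated
  tiny <- PGI_TRUTH; tiny[["vf"]] <- 1e-12
  expect_equal(residuals_global(tiny, prob), -dat$rate, tolerance = 1e-9)
  # hand-computed residuals for 3 samples at shifted parameters
  sub <- dat[c(3, 10, 20), ]
  prob3 <- global_fit_problem("pgi", sub, free = PGI_TRUTH, fixed = c(h = 1),
                              seed = 1)
  th <- c(vf = 3.0, k_G6P = 0.6, k_F6P = 0.2, keq = 0.3)
  by_hand <- vapply(1:3, function(i)
    oracle_rev_mm(sub$G6P[i], sub$F6P[i], 3.0, 0.6, 0.2, 0.3) - sub$rate[i],
    0)
  expect_equal(unname(residuals_global(th, prob3)), by_hand, tolerance = 1e-12)
})

test_that("single free Vf has the closed-form least-squares solution", {
  # v = vf * s/(ks+s) with ks fixed: vf_hat = sum(v_i g_i)/sum(g_i^2),
  # g = s/(ks+s)
  dat <- data.frame(rate = c(0.5, 0.9, 1.4), weight = 1, S = c(0.5, 1, 4))
  g <- dat$S / (0.7 + dat$S)
  vf_hat <- sum(dat$rate * g) / sum(g^2)
  prob <- global_fit_problem("mm", dat, free = c(vf = 1), fixed = c(k_S = 0.7),
                             seed = 3)
  fit <- fit_global(prob, ga_control(generations = 20))
  expect_equal(unname(fit$par[["vf"]]), vf_hat, tolerance = 1e-8)
})

test_that("fit_global agrees with a brute-force lattice oracle on 2 parameters", {
  dat <- pgi_grid_dataset()
  fixed <- c(k_F6P = 0.152, keq = 0.286, h = 1)
  lower <- c(vf = 0.5, k_G6P = 0.05); upper <- c(vf = 20, k_G6P = 5)
  oracle <- oracle_grid_fit(dat, c("vf", "k_G6P"), fixed, lower, upper,
                            nlat = 60L)
  prob <- global_fit_problem("pgi", dat, free = c(vf = 2, k_G6P = 0.2),
                             fixed = fixed, lower = lower, upper = upper,
                             seed = 11)
  fit <- fit_global(prob, ga_control(generations = 60))
  # both must land on the generating optimum; lattice resolution bounds the
  # oracle's own error
  expect_equal(unname(fit$par), unname(oracle), tolerance = 0.05)
  expect_equal(unname(fit$par[["vf"]]), 3.551, tolerance = 1e-6)
  expect_equal(unname(fit$par[["k_G6P"]]), 0.550, tolerance = 1e-6)
})

test_that("fits are bitwise deterministic given problem and seed", {
  dat <- pgi_grid_dataset()
  mk <- function() global_fit_problem(
    "pgi", dat, free = c(vf = 1, k_G6P = 0.2, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 77)
  f1 <- fit_global(mk(), ga_control(generations = 30))
  f2 <- fit_global(mk(), ga_control(generations = 30))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$rss, f2$rss)
})

test_that("refined solution never worsens the GA optimum and stays in bounds", {
  dat <- pgi_grid_dataset()
  prob <- global_fit_problem(
    "pgi", dat, free = c(vf = 1, k_G6P = 0.2, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 5)
  fit <- fit_global(prob, ga_control(generations = 40))
  expect_lte(fit$rss, fit$ga_rss + 1e-12)
  expect_true(all(fit$par >= prob$lower & fit$par <= prob$upper))
})

test_that("rate scaling multiplies Vf and leaves other parameters unchanged", {
  dat <- pgi_grid_dataset()
  prob <- global_fit_problem(
    "pgi", dat, free = c(vf = 1, k_G6P = 0.2, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 5)
  fit <- fit_global(prob, ga_control(generations = 40))
  dat2 <- dat; dat2$rate <- 2.5 * dat$rate
  prob2 <- global_fit_problem(
    "pgi", dat2, free = c(vf = 1, k_G6P = 0.2, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 5)
  fit2 <- fit_global(prob2, ga_control(generations = 40))
  expect_equal(unname(fit2$par[["vf"]] / fit$par[["vf"]]), 2.5,
               tolerance = 1e-6)
  for (nm in c("k_G6P", "k_F6P", "keq"))
    expect_equal(fit2$par[[nm]], fit$par[[nm]], tolerance = 1e-6)
})

test_that("parameter errors follow the residual-variance-scaled covariance", {
  # linear model v = a * S through a custom law: SEM closed form
  # sqrt(RSS/(n-1)) / sqrt(sum(S^2))
  register_rate_law(define_rate_law(
    "linear", reaction_scheme("S", character()),
    function(conc, theta) theta[["a"]] * conc$S))
  on.exit(rm("linear", envir = nmrkin:::.law_registry))
  set.seed(9)
  S <- seq(0.5, 5, length.out = 30)
  v <- 2 * S + rnorm(30, 0, 0.15)
  dat <- data.frame(rate = v, weight = 1, S = S)
  prob <- global_fit_problem("linear", dat, free = c(a = 1), seed = 2)
  fit <- fit_global(prob, ga_control(generations = 20))
  a_hat <- sum(v * S) / sum(S^2)
  expect_equal(unname(fit$par[["a"]]), a_hat, tolerance = 1e-7)
  sem_closed <- sqrt(sum((v - a_hat * S)^2) / (30 - 1)) / sqrt(sum(S^2))
  expect_equal(unname(parameter_errors(fit)[["a"]]), sem_closed,
               tolerance = 1e-4)

  # zero residuals -> zero SEM
  dat0 <- data.frame(rate = 2 * S, weight = 1, S = S)
  fit0 <- fit_global(global_fit_problem("linear", dat0, free = c(a = 1),
                                        seed = 2),
                     ga_control(generations = 10))
  expect_lt(max(parameter_errors(fit0)), 1e-7)

  # duplicating every sample at identical per-point RSS shrinks SEM by
  # sqrt((n-p)/(2n-p))
  dat2 <- rbind(dat, dat)
  fit2 <- fit_global(global_fit_problem("linear", dat2, free = c(a = 1),
                                        seed = 2),
                     ga_control(generations = 10))
  expect_equal(unname(fit2$sem[["a"]] / fit$sem[["a"]]),
               sqrt((30 - 1) / (60 - 1)), tolerance = 1e-3)

  # SEM is invariant under sample reordering
  datr <- dat[sample(30), ]
  fitr <- fit_global(global_fit_problem("linear", datr, free = c(a = 1),
                                        seed = 2),
                     ga_control(generations = 10))
  expect_equal(fitr$sem, fit$sem, tolerance = 1e-6)
})

test_that("rank-deficient problems flag unidentifiable directions", {
  # two parameters entering only through their product: J is rank 1
  register_rate_law(define_rate_law(
    "prod2", reaction_scheme("S", character()),
    function(conc, theta) theta[["a"]] * theta[["b"]] * conc$S))
  on.exit(rm("prod2", envir = nmrkin:::.law_registry))
  S <- seq(1, 5, length.out = 12)
  dat <- data.frame(rate = 3 * S, weight = 1, S = S)
  prob <- global_fit_problem("prod2", dat, free = c(a = 1.5, b = 2), seed = 4)
  fit <- fit_global(prob, ga_control(generations = 0), multistart = FALSE)
  expect_true(fit$rank_deficient)
  expect_true(any(!is.finite(fit$sem)))
})

test_that("R-squared behaves like a coefficient of determination", {
  dat <- pgi_grid_dataset()
  prob <- global_fit_problem("pgi", dat, free = PGI_TRUTH, fixed = c(h = 1),
                             seed = 1)
  fit <- fit_global(prob, ga_control(generations = 0))
  expect_equal(fit$r2, 1, tolerance = 1e-10)   # perfect fit
  expect_equal(goodness_of_fit(fit), fit$r2, tolerance = 1e-12)
  # constant model at the mean scores 0: force vf ~ 0 so v ~ 0, then compare
  # against a dataset whose rates are centred
  datc <- dat; datc$rate <- dat$rate - mean(dat$rate)
  probc <- global_fit_problem("pgi", datc, free = PGI_TRUTH, fixed = c(h = 1),
                              seed = 1)
  fitc <- fit_global(probc, ga_control(generations = 0))
  fitc$par[["vf"]] <- 1e-12   # model ~ 0 = mean of centred rates
  expect_equal(goodness_of_fit(fitc), 0, tolerance = 1e-6)
  # zero-variance dataset is flagged
  datz <- dat; datz$rate <- 1
  probz <- global_fit_problem("pgi", datz, free = PGI_TRUTH, fixed = c(h = 1),
                              seed = 1)
  fitz <- fit_global(probz, ga_control(generations = 0))
  expect_error(goodness_of_fit(fitz), "zero-variance")
})

test_that("problem construction validates its inputs", {
  dat <- pgi_grid_dataset()
  expect_error(global_fit_problem("pgi", dat[0, ], free = c(vf = 1)), "nrow")
  expect_error(global_fit_problem("pgi", dat, free = c(nope = 1)),
               "not used by law")
  expect_error(global_fit_problem("pgi", dat[, -3], free = c(vf = 1)),
               "lacks concentration")
  expect_error(global_fit_problem("pgi", dat, free = c(vf = 1),
                                  lower = c(vf = 2), upper = c(vf = 3)),
               "inside the bounds")
  p1 <- global_fit_problem("pgi", dat, free = c(vf = 1, k_G6P = 1, k_F6P = 1,
                                                keq = 1), fixed = c(h = 1))
  expect_error(fit_global(global_fit_problem(
    "pgi", dat[1:3, ], free = c(vf = 1, k_G6P = 1, k_F6P = 1, keq = 1),
    fixed = c(h = 1))), "more samples than")
  expect_s3_class(p1, "fit_problem")
})

test_that("truncation scan removes per-assay tails and reports both dof conventions", {
  sim <- simulate_noisy_timecourses(pgi_scenario(n_times = 20L))
  dat <- build_rate_dataset(sim$curves, pgi_scheme())
  prob <- global_fit_problem(
    "pgi", dat, free = c(vf = 0.5, k_G6P = 0.3, k_F6P = 0.3, keq = 0.5),
    fixed = c(h = 1), seed = 13)
  scan <- truncation_scan(prob, 6, ga = ga_control(generations = 60))
  s <- scan$steps
  # step 0 is the baseline fit
  expect_equal(s$vf[1], unname(scan$baseline$par[["vf"]]))
  expect_equal(s$n[1], nrow(dat))
  # removed counts strictly increase; per step k each of 5 assays loses k
  expect_equal(s$removed_total, 0:6 * 5)
  expect_true(all(diff(s$removed_total) > 0))
  # latest times go first
  kept1 <- scan$fits[[2]]$problem$data
  expect_equal(max(kept1$time[kept1$assay_id == "fwd10"]),
               sort(dat$time[dat$assay_id == "fwd10"], decreasing = TRUE)[2])
  # both SEM conventions present and related by the dof ratio
  expect_equal(s$sem_original_keq[3] / s$sem_rescaled_keq[3],
               sqrt((s$n[3] - 4) / (s$n[1] - 4)))
  expect_error(truncation_scan(prob, 20), "shorter|smaller")
})

test_that("fit results serialize to JSON with covariance and metadata", {
  dat <- pgi_grid_dataset()
  fit <- fit_global(global_fit_problem("pgi", dat, free = PGI_TRUTH,
                                       fixed = c(h = 1), seed = 1),
                    ga_control(generations = 0))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$parameters$vf, unname(fit$par[["vf"]]), tolerance = 1e-12)
  expect_equal(obj$n, nrow(dat))
  expect_true(is.numeric(unlist(obj$covariance)))
  expect_equal(obj$seed, 1)
})
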