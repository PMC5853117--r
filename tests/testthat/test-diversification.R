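profile_from_g <- function(g) {
  # build a profile through the public route: a caterpillar tree with the
  # requested internode intervals
  n <- length(g) + 1L
  b <- rev(cumsum(rev(g)))                 # b_1 > ... > b_{n-1}
  nwk <- sprintf("(t1:%.10f,t2:%.10f)", b[n - 1L], b[n - 1L])
  if (n > 2) for (k in seq.int(n - 2L, 1L))
    nwk <- sprintf("(%s:%.10f,t%d:%.10f)", nwk, b[k] - (if (k == n - 1L) 0
      else b[k + 1L]), n - k + 1L, b[k])
  branching_profile(read_timetree(paste0(nwk, ";")))
}

test_that("gamma matches the hand-computed worked examples", {
  expect_equal(gamma_stat(profile_from_g(c(1, 1))), -0.346410,
               tolerance = 1e-6)
  expect_equal(gamma_stat(profile_from_g(c(1, 1, 1))), -0.544331,
               tolerance = 1e-6)
  expect_error(gamma_stat(read_timetree("(A:1,B:1);")), "splits|3")
})

test_that("gamma agrees with an independent direct-loop implementation", {
  set.seed(701)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    b <- sort(stats::runif(n - 1, 0.01, 20), decreasing = TRUE)
    g <- c(-diff(b), b[n - 1])
    expect_equal(gamma_stat(profile_from_g(g)), gamma_direct(b),
                 tolerance = 1e-8)
  }
})

test_that("gamma agrees with the reference implementation on trees", {
  set.seed(702)
  for (i in 1:30) {
    tr <- random_ultra_tree(sample(5:60, 1))
    expect_equal(gamma_stat(branching_profile(tr)), ape::gammaStat(tr),
                 tolerance = 1e-8)
  }
})

test_that("gamma p-values reproduce the published conversions", {
  expect_equal(round(gamma_pvalue(1.45, "two"), 3), 0.147)
  expect_equal(round(gamma_pvalue(-2.09, "two"), 3), 0.037)
  expect_equal(round(gamma_pvalue(-0.348, "one_lower"), 2), 0.36)
  expect_equal(round(gamma_pvalue(-0.88, "one_lower"), 2), 0.19)
  expect_equal(round(gamma_pvalue(-1.25, "one_lower"), 2), 0.11)
  expect_equal(round(gamma_pvalue(-0.45, "one_lower"), 2), 0.33)
  expect_equal(gamma_pvalue(0, "two"), 1)
  expect_error(gamma_pvalue(NaN), "finite")
})

test_that("pure-birth fit matches the closed form and hand example", {
  p <- profile_from_g(c(1, 1))
  fit <- fit_pure_birth(p)
  expect_equal(fit$params$lambda, 0.2)
  expect_equal(fit$lnL, log(0.4) - 1, tolerance = 1e-9)
  expect_equal(fit$AIC, 5.832581, tolerance = 1e-5)
  # numerical-optimization oracle on the pure-birth likelihood formula
  n <- p$n; Ttot <- p$Ttot
  lnl <- function(l) sum(log((2:(n - 1)) * l)) - l * Ttot
  opt <- stats::optimize(lnl, c(1e-6, 10), maximum = TRUE)
  expect_equal(fit$params$lambda, opt$maximum, tolerance = 1e-4)
  expect_equal(fit$lnL, opt$objective, tolerance = 1e-8)
})

test_that("doubling all times halves the pure-birth rate estimate", {
  set.seed(703)
  tr <- simulate_yule(30)
  f1 <- fit_pure_birth(branching_profile(tr))
  tr$edge.length <- tr$edge.length * 2
  f2 <- fit_pure_birth(branching_profile(tr))
  expect_equal(f2$params$lambda, f1$params$lambda / 2, tolerance = 1e-9)
})

test_that("birth-death nests pure birth and matches it at a = 0", {
  set.seed(704)
  for (i in 1:10) {
    p <- branching_profile(simulate_yule(sample(10:60, 1)))
    pb <- fit_pure_birth(p)
    expect_equal(divshift:::bd_loglik(p, pb$params$lambda, 0), pb$lnL,
                 tolerance = 1e-6)
    bd <- fit_birth_death(p)
    expect_gte(bd$lnL, pb$lnL - 1e-6)
  }
})

test_that("birth-death fit agrees with the reference implementation", {
  set.seed(705)
  tr <- ape::rphylo(120, birth = 0.4, death = 0.2)
  bd <- fit_birth_death(branching_profile(tr))
  ref <- ape::birthdeath(tr)
  expect_equal(bd$lnL, -ref$dev / 2, tolerance = 1e-3)
  expect_equal(unname(bd$params$a), unname(ref$para["d/b"]),
               tolerance = 0.02)
  expect_equal(unname(bd$params$r), unname(ref$para["b-d"]),
               tolerance = 0.02)
})

test_that("extinction-fraction recovery stays near the truth", {
  set.seed(706)
  a_hat <- replicate(100, {
    tr <- ape::rphylo(200, birth = 0.4, death = 0.2)
    fit_birth_death(branching_profile(tr))$params$a
  })
  expect_lt(abs(stats::median(a_hat) - 0.5), 0.15)
})

test_that("density-dependent models reduce to pure birth at the boundary", {
  set.seed(707)
  p <- branching_profile(simulate_yule(40))
  pb <- fit_pure_birth(p)
  n <- p$n; k <- 2:n
  # DDX with x pinned to 0 is exactly pure birth
  expect_equal(divshift:::profile_loglik(p, pb$params$lambda * k^0), pb$lnL,
               tolerance = 1e-9)
  # DDL at K = 10 n is within half a unit of pure birth on Yule data
  ck <- 1 - k / (10 * n)
  r <- (n - 2) / sum(k * ck * p$g)
  expect_lt(abs(divshift:::profile_loglik(p, r * ck) - pb$lnL), 0.5)
  # fitted DD models never fall below the nested pure-birth likelihood
  expect_gte(fit_density_dependent(p, "DDL")$lnL, pb$lnL - 1e-6)
  expect_gte(fit_density_dependent(p, "DDX")$lnL, pb$lnL - 1e-6)
  expect_error(fit_density_dependent(p, "nope"))
})

test_that("model comparison table is internally consistent", {
  set.seed(708)
  cm <- compare_models(branching_profile(simulate_yule(50)))
  expect_setequal(cm$table$model, c("pure_birth", "birth_death", "DDL",
                                    "DDX"))
  expect_equal(cm$table$AIC, 2 * cm$table$n_params - 2 * cm$table$lnL)
  aic <- stats::setNames(cm$table$AIC, cm$table$model)
  expect_equal(cm$dAIC, min(aic[c("pure_birth", "birth_death")]) -
                 min(aic[c("DDL", "DDX")]))
})

test_that("constant-rate data mostly select a constant-rate model", {
  set.seed(709)
  best <- replicate(25, {
    cm <- compare_models(branching_profile(simulate_yule(60)))
    cm$best_model %in% c("pure_birth", "birth_death")
  })
  expect_gt(mean(best), 0.5)
})

test_that("strong density-dependent slowdowns select DDL", {
  set.seed(710)
  wins <- replicate(25, {
    tr <- divshift:::simulate_ddl_tree(50, r = 0.5, K = 60)
    compare_models(branching_profile(tr))$dAIC > 0
  })
  expect_gt(mean(wins), 0.6)
})

test_that("yule simulation honors its sampling contract", {
  tr <- simulate_yule(115, seed = 8)
  expect_equal(ape::Ntip(tr), 115L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(write_timetree(simulate_yule(20, seed = 9)),
                   write_timetree(simulate_yule(20, seed = 9)))
  expect_error(simulate_yule(2), "n_tips")
})

test_that("yule internode intervals have mean 1/(k lambda)", {
  set.seed(711)
  lambda <- 0.7; n <- 6; reps <- 4000
  G <- replicate(reps, branching_profile(simulate_yule(n, lambda = lambda))$g)
  for (j in seq_len(n - 1)) {
    k <- j + 1
    se <- 1 / (k * lambda) / sqrt(reps)
    expect_lt(abs(mean(G[j, ]) - 1 / (k * lambda)), 3.5 * se)
  }
})

test_that("gamma is approximately standard normal under pure birth", {
  set.seed(712)
  g <- vapply(1:3000, function(i)
    gamma_stat(branching_profile(simulate_yule(40))), 0)
  expect_lt(abs(mean(g)), 3.5 / sqrt(3000))
  expect_lt(abs(stats::var(g) - 1), 0.12)
  # two-tailed test at the normal 1.96 threshold rejects ~5%
  expect_lt(abs(mean(abs(g) > 1.96) - 0.05), 0.02)
})

test_that("sensitivity grid reports ns for unremarkable statistics", {
  set.seed(713)
  out <- sensitivity_missing(-0.1, function(tr) gamma_stat(tr),
                             n_tips = 40, n_sim = 300, f_max = 0.3)
  expect_false(out$significant)
  expect_true(is.na(out$max_f))
  expect_equal(nrow(out$grid), 1L)
})

test_that("a planted strong slowdown survives some missing taxa", {
  set.seed(714)
  tr <- divshift:::simulate_ddl_tree(60, r = 1, K = 63)
  g_obs <- gamma_stat(branching_profile(tr))
  expect_lt(g_obs, -2)
  out <- sensitivity_missing(g_obs, function(t) gamma_stat(t),
                             n_tips = 60, n_sim = 400, f_max = 0.3,
                             seed = 15)
  expect_true(out$significant)
  expect_gte(out$max_f, 0.1)
})
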