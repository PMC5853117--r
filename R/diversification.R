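# Diversification-rate analysis on branching profiles: the Pybus-Harvey
# gamma statistic with normal p-values, maximum-likelihood fits of
# constant-rate (pure birth, birth-death) and density-dependent (DDL, DDX)
# branching models compared by AIC, pure-birth tree simulation, and the
# missing-taxon sensitivity procedure (simulate, prune, compare).

#' Pybus-Harvey gamma statistic
#'
#' `gamma = [ mean(T_i, i = 2..n-1) - T/2 ] / [ T * sqrt(1/(12(n-2))) ]`
#' where `T_i` are the cumulative lineage-weighted interval sums of the
#' branching profile and `T = T_n`. Asymptotically standard normal under a
#' constant-rate pure-birth process with complete sampling; negative values
#' indicate branching concentrated early (a diversification slowdown).
#'
#' @param profile an `ltt_profile` from [branching_profile()], or a `phylo`
#'   (profiled at the present).
#' @return the gamma statistic (dimensionless scalar).
#' @export
gamma_stat <- function(profile) {
  if (inherits(profile, "phylo")) profile <- branching_profile(profile)
  n <- profile$n
  if (n < 3L) stop("gamma requires at least 3 lineages")
  Ttot <- profile$Ttot
  if (Ttot <= 0) stop("total weighted interval sum must be positive")
  inner <- mean(profile$Tcum[seq_len(n - 2L)])   # T_2 .. T_{n-1}
  (inner - Ttot / 2) / (Ttot * sqrt(1 / (12 * (n - 2L))))
}

#' P-value for a gamma statistic under its standard-normal null
#'
#' @param gamma the observed statistic.
#' @param tails `"two"` for the usual two-tailed test, or `"one_lower"` for
#'   the one-tailed probability of a value this low (slowdown direction).
#' @return p-value in `[0, 1]`.
#' @export
gamma_pvalue <- function(gamma, tails = c("two", "one_lower")) {
  tails <- match.arg(tails)
  if (!is.finite(gamma)) stop("gamma must be finite")
  switch(tails,
         two = 2 * stats::pnorm(-abs(gamma)),
         one_lower = stats::pnorm(gamma))
}

# shared skeleton for the four branching-model fits
new_divfit <- function(model, params, lnL) {
  k <- length(params)
  structure(list(model = model, params = params, lnL = lnL,
                 n_params = k, AIC = 2 * k - 2 * lnL),
            class = "diversification_fit")
}

#' @export
print.diversification_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, AIC = %.4f\n  params: %s\n",
              x$model, x$lnL, x$AIC,
              paste(names(x$params), signif(unlist(x$params), 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

# log-likelihood of a branching profile given per-k speciation rates
# lambda_k (k = 2..n): sum ln(k lambda_k) over k = 2..n-1 minus the
# survival term sum k lambda_k g_k over k = 2..n (the final interval g_n
# down to the cut line is part of the probability model).
profile_loglik <- function(profile, lambda_k) {
  n <- profile$n
  k <- seq.int(2L, n)
  if (any(lambda_k <= 0)) return(-Inf)
  sum(log(k[-length(k)] * lambda_k[-length(k)])) -
    sum(k * lambda_k * profile$g)
}

#' Fit a constant-rate pure-birth (Yule) model to a branching profile
#'
#' Closed form: `lambda_hat = (n - 2) / T`.
#'
#' @param profile an `ltt_profile` (or `phylo`).
#' @return a `diversification_fit` (1 free parameter).
#' @export
fit_pure_birth <- function(profile) {
  if (inherits(profile, "phylo")) profile <- branching_profile(profile)
  if (profile$Ttot <= 0) stop("zero total lineage time")
  lambda <- (profile$n - 2L) / profile$Ttot
  lnL <- profile_loglik(profile, rep(lambda, profile$n - 1L))
  new_divfit("pure_birth", list(lambda = lambda), lnL)
}

# Nee-style constant-rate birth-death log-likelihood of branching times,
# conditioned on the crown age and survival of both crown lineages,
# parameterized by net rate r = lambda - mu and extinction fraction
# a = mu / lambda. Reduces exactly to the pure-birth likelihood at a = 0
# (same (n-1)! constant as profile_loglik with constant rates).
bd_loglik <- function(profile, r, a) {
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  x <- profile$btimes                     # b_1 (crown) > ... > b_{n-1}
  n <- profile$n
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(x[-1L]) +
    n * log1p(-a) - 2 * sum(log(exp(r * x) - a))
}

#' Fit a constant-rate birth-death model to a branching profile
#'
#' Maximizes the Nee et al. crown-conditioned likelihood over the net
#' diversification rate `r > 0` and extinction fraction `a in [0, 1)`,
#' using multi-start bounded optimization on (log r, a). A fit pinned at
#' the `a -> 1` boundary is flagged in `$boundary`.
#'
#' @param profile an `ltt_profile` (or `phylo`).
#' @return a `diversification_fit` (2 free parameters).
#' @export
fit_birth_death <- function(profile) {
  if (inherits(profile, "phylo")) profile <- branching_profile(profile)
  pb <- fit_pure_birth(profile)
  obj <- function(par) -bd_loglik(profile, exp(par[1]), par[2])
  starts <- expand.grid(logr = log(pb$params$lambda) + c(-1, 0, 1),
                        a = c(0.05, 0.5, 0.9))
  best <- list(value = -(pb$lnL))         # a = 0 start: the nested PB fit
  best_par <- c(log(pb$params$lambda), 0)
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = c(-30, 0), upper = c(30, 1 - 1e-9),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(o) && o$value < best$value - 1e-12) {
      best <- o; best_par <- o$par
    }
  }
  r <- exp(best_par[1]); a <- best_par[2]
  fit <- new_divfit("birth_death", list(r = r, a = a), -best$value)
  fit$boundary <- a > 1 - 1e-6
  fit
}

#' Fit a density-dependent diversification model to a branching profile
#'
#' While `k` lineages exist the speciation rate is
#' `lambda_k = r (1 - k / K)` (DDL, logistic; carrying capacity `K > n`) or
#' `lambda_k = r * k^(-x)` (DDX, exponential; `x in [0, 5]`). For fixed
#' shape parameter the rate scale `r` has a closed-form MLE, so the fit is
#' a 1-D profile-likelihood search (K on a log scale in `(n, 1e6]`).
#' DDL with `K -> Inf` and DDX with `x = 0` reduce to pure birth.
#'
#' @param profile an `ltt_profile` (or `phylo`).
#' @param form `"DDL"` or `"DDX"`.
#' @return a `diversification_fit` (2 free parameters); `$boundary` flags a
#'   solution at the feasibility edge.
#' @export
fit_density_dependent <- function(profile, form = c("DDL", "DDX")) {
  form <- match.arg(form)
  if (inherits(profile, "phylo")) profile <- branching_profile(profile)
  n <- profile$n
  k <- seq.int(2L, n)
  # profile likelihood: for shape c_k, r_hat = (n-2) / sum(k c_k g_k)
  prof_lnL <- function(ck) {
    denom <- sum(k * ck * profile$g)
    if (denom <= 0 || any(ck[-length(ck)] <= 0)) return(-Inf)
    r <- (n - 2) / denom
    profile_loglik(profile, r * ck)
  }
  if (form == "DDL") {
    shape <- function(s) 1 - k / (n + exp(s))    # K = n + exp(s) > n
    lo <- log(1e-3); hi <- log(1e8)              # hi ~ pure-birth limit
  } else {
    shape <- function(s) k^(-s)                  # x = s
    lo <- 0; hi <- 5
  }
  o <- stats::optimize(function(s) -prof_lnL(shape(s)),
                       lower = lo, upper = hi, tol = 1e-9)
  # compare the interior optimum with the pure-birth boundary
  cand <- c(o$minimum, hi)
  vals <- vapply(cand, function(s) -prof_lnL(shape(s)), 0)
  s <- cand[which.min(vals)]
  ck <- shape(s)
  r <- (n - 2) / sum(k * ck * profile$g)
  params <- if (form == "DDL") list(r = r, K = n + exp(s))
            else list(r = r, x = s)
  fit <- new_divfit(form, params, prof_lnL(ck))
  fit$boundary <- abs(s - hi) < 1e-6 || abs(s - lo) < 1e-6
  fit
}

#' Fit and compare all four diversification models
#'
#' @param profile an `ltt_profile` (or `phylo`).
#' @return list with `table` (data.frame: model, parameter string, lnL,
#'   n_params, AIC), `best_model` (lowest AIC), `fits`, and `dAIC` =
#'   AIC(best constant-rate) - AIC(best density-dependent); positive values
#'   favor density dependence.
#' @export
compare_models <- function(profile) {
  if (inherits(profile, "phylo")) profile <- branching_profile(profile)
  fits <- list(pure_birth = fit_pure_birth(profile),
               birth_death = fit_birth_death(profile),
               DDL = fit_density_dependent(profile, "DDL"),
               DDX = fit_density_dependent(profile, "DDX"))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model,
               params = paste(names(f$params),
                              signif(unlist(f$params), 6),
                              sep = "=", collapse = ", "),
               lnL = f$lnL, n_params = f$n_params, AIC = f$AIC)))
  rownames(tab) <- NULL
  aic <- vapply(fits, `[[`, 0, "AIC")
  dAIC <- min(aic[c("pure_birth", "birth_death")]) - min(aic[c("DDL", "DDX")])
  list(table = tab, fits = fits,
       best_model = tab$model[which.min(tab$AIC)], dAIC = dAIC)
}

#' Simulate a pure-birth (Yule) tree conditioned on tip count
#'
#' Grows from 2 crown lineages with exponential waiting times at total rate
#' `k * lambda`; a uniformly chosen lineage splits at each event. After the
#' n-th lineage appears a final `Exp(n * lambda)` interval is appended so
#' every internode interval satisfies `E[g_k] = 1/(k * lambda)`. Tips sit
#' at age 0.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed optional integer for reproducibility.
#' @param lambda speciation rate (events / Ma); gamma is invariant to it.
#' @return an ultrametric `phylo`.
#' @export
simulate_yule <- function(n_tips, seed = NULL, lambda = 1) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  g <- stats::rexp(n - 1L, rate = seq.int(2L, n) * lambda)  # g_2 .. g_n
  split_t <- cumsum(c(0, g[-(n - 1L)]))   # forward times of splits 1..n-1
  total <- sum(g)
  # actives: stub parent node id and its forward time
  par_id <- integer(n); par_t <- numeric(n)
  par_id[1:2] <- n + 1L; par_t[1:2] <- 0
  n_act <- 2L
  edge <- matrix(0L, 2L * n - 2L, 2L); elen <- numeric(2L * n - 2L); ne <- 0L
  for (j in seq_len(n - 2L)) {            # splits creating nodes n+2..2n-1
    i <- sample.int(n_act, 1L)
    node <- n + 1L + j
    ne <- ne + 1L
    edge[ne, ] <- c(par_id[i], node); elen[ne] <- split_t[j + 1L] - par_t[i]
    par_id[i] <- node; par_t[i] <- split_t[j + 1L]
    n_act <- n_act + 1L
    par_id[n_act] <- node; par_t[n_act] <- split_t[j + 1L]
  }
  for (i in seq_len(n)) {                 # close every lineage as a tip
    ne <- ne + 1L
    edge[ne, ] <- c(par_id[i], i); elen[ne] <- total - par_t[i]
  }
  out <- list(edge = edge, edge.length = elen,
              tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Missing-taxon sensitivity of a diversification statistic
#'
#' For each assumed missing fraction `f` on a grid, simulates pure-birth
#' trees with `round(n_tips / (1 - f))` tips, prunes random tips down to
#' `n_tips`, computes the statistic on each, and asks whether the observed
#' value stays outside the simulated null at level `alpha` (two-tailed
#' quantiles for gamma; upper one-tailed for a delta-AIC statistic). The
#' grid is climbed until the first non-significant `f`.
#'
#' @param observed the observed statistic on the real tree.
#' @param statistic_fn function(`phylo`) -> scalar (e.g. [gamma_stat()], or
#'   a wrapper returning `compare_models(t)$dAIC`).
#' @param n_tips tip count of the observed tree.
#' @param alpha significance level (default 0.05).
#' @param tails `"two"` (gamma) or `"one_upper"` (dAIC).
#' @param n_sim simulated trees per grid point (default 10000).
#' @param f_step grid increment for the missing fraction (default 0.1).
#' @param f_max largest missing fraction examined (default 0.9).
#' @param seed optional integer.
#' @return list with `max_f` (largest significant missing fraction, or `NA`
#'   and `significant = FALSE` if not significant even at f = 0) and a
#'   per-grid-point data.frame of critical values.
#' @export
sensitivity_missing <- function(observed, statistic_fn, n_tips, alpha = 0.05,
                                tails = c("two", "one_upper"),
                                n_sim = 10000, f_step = 0.1, f_max = 0.9,
                                seed = NULL) {
  tails <- match.arg(tails)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, f_max, by = f_step)
  rows <- list(); max_f <- NA_real_; sig_any <- FALSE
  for (f in grid) {
    n_full <- max(n_tips + 3L, round(n_tips / (1 - f)))
    k <- n_full - n_tips
    stat <- vapply(seq_len(n_sim), function(i) {
      tr <- simulate_yule(n_full)
      if (k > 0) tr <- prune_random_tips(tr, k)
      statistic_fn(tr)
    }, 0)
    if (tails == "two") {
      crit <- stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      sig <- observed < crit[1] || observed > crit[2]
      rows[[length(rows) + 1L]] <- data.frame(
        f = f, lower = crit[1], upper = crit[2], significant = sig)
    } else {
      crit <- stats::quantile(stat, 1 - alpha, names = FALSE)
      sig <- observed > crit
      rows[[length(rows) + 1L]] <- data.frame(
        f = f, lower = NA_real_, upper = crit, significant = sig)
    }
    if (!sig) break
    sig_any <- TRUE; max_f <- f
  }
  list(significant = sig_any, max_f = if (sig_any) max_f else NA_real_,
       grid = do.call(rbind, rows))
}
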