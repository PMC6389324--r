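# Poisson random field machinery: expected SFS entries under scaled
# selection S, Gamma(+exponential) DFE integration, maximum-likelihood
# fitting with per-frequency-class nuisance multipliers r_i, and the derived
# adaptive/nonadaptive substitution rates alpha, omega_a, omega_na.

#' Relative fixation rate S / (1 - exp(-S))
#'
#' Probability of fixation of a new mutation with scaled coefficient S
#' relative to a neutral one; `f(0) = 1` by continuity. Also used as the
#' gBGC fixation bias with `S = +/-B`.
#'
#' @param S Numeric vector of scaled coefficients.
#' @return Numeric vector of the same length.
#' @export
fixation_factor <- function(S) {
  out <- numeric(length(S))
  small <- abs(S) < 1e-8
  out[small] <- 1 + S[small] / 2
  big_pos <- S >= 700
  out[big_pos] <- S[big_pos]
  big_neg <- S <= -700
  out[big_neg] <- 0
  mid <- !small & !big_pos & !big_neg
  out[mid] <- S[mid] / (-expm1(-S[mid]))
  out
}

# Gauss-Legendre nodes/weights on (0,1) by Golub-Welsch (cached per order).
gauss_legendre_01 <- function(order = 64L) {
  key <- paste0("gl", order)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  k <- seq_len(order - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, order, order)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2                 # map [-1,1] -> [0,1]
  w <- 2 * e$vectors[1, ]^2 / 2
  o <- order(x)
  res <- list(x = x[o], w = w[o])
  .codon_cache[[key]] <- res
  res
}

# log(1 - exp(-a)) for a > 0, stable.
log1mexp <- function(a) ifelse(a < log(2), log(-expm1(-a)), log1p(-exp(-a)))

# Stable sojourn ratio (1 - exp(-S(1-x))) / (1 - exp(-S)) = H(S, x) * x(1-x),
# vectorised over x (S scalar). Equals (1 - x) at S = 0.
sojourn_ratio <- function(S, x) {
  if (abs(S) < 1e-8) return(1 - x)
  if (S > 0) return(-expm1(-S * (1 - x)) / -expm1(-S))
  T <- -S
  # (e^{T(1-x)} - 1) / (e^T - 1), computed in log space
  a <- T * (1 - x)
  lr <- -T * x + log1mexp(a) - log1mexp(T)
  lr[a < 1e-12] <- log(a[a < 1e-12]) - T - log1mexp(T)
  exp(lr)
}

#' Expected unfolded-SFS entry under the Poisson random field
#'
#' Expected relative density of segregating sites at derived count i in a
#' sample of n chromosomes for a mutation with scaled selection coefficient
#' S: `choose(n,i) * integral_0^1 H(S,x) x^i (1-x)^(n-i) dx`, with sojourn
#' density `H(S,x) = (1-exp(-S(1-x))) / ((1-exp(-S)) x (1-x))` and
#' `H(0,x) = 1/x` by continuity, so the neutral value is `1/i`. Evaluation
#' uses fixed-order Gauss-Legendre quadrature, with the domain truncated to
#' the boundary layer `x <= 30/|S|` for strongly deleterious S where the
#' integrand decays as `exp(Sx)`.
#'
#' @param S Scaled selection coefficient (scalar).
#' @param i Derived-allele count(s), in 1..n-1 (vectorised).
#' @param n Sample size (chromosomes), >= 2.
#' @param order Quadrature order (default 64).
#' @return Nonnegative numeric vector, one value per `i`.
#' @export
expected_sfs_entry <- function(S, i, n, order = 64L) {
  stopifnot(n >= 2, all(i >= 1L & i <= n - 1L))
  gl <- gauss_legendre_01(order)
  upper <- if (S < -30) min(1, 30 / abs(S)) else 1
  x <- gl$x * upper
  w <- gl$w * upper
  hr <- sojourn_ratio(S, x)
  # integrand_i(x) = hr * choose(n,i) x^(i-1) (1-x)^(n-i-1)
  out <- vapply(i, function(ii) {
    sum(w * hr * exp(lchoose(n, ii) + (ii - 1) * log(x) + (n - ii - 1) * log1p(-x)))
  }, numeric(1))
  out
}

#' DFE model specification
#'
#' `GammaZero` models the deleterious DFE as a Gamma distribution of
#' absolute scaled effects (shape, mean); `GammaExpo` adds a beneficial
#' class: with probability `p_pos` effects are positive, exponentially
#' distributed with mean `mean_pos`. GammaZero is nested in GammaExpo at
#' `p_pos = 0`.
#'
#' @param name `"GammaZero"` or `"GammaExpo"`.
#' @param shape,mean Gamma shape and mean of |S| for the deleterious class.
#' @param p_pos,mean_pos Probability and exponential mean of the beneficial
#'   class (GammaExpo only).
#' @return Object of class `dfe_model`.
#' @export
dfe_model <- function(name = c("GammaZero", "GammaExpo"),
                      shape = 0.4, mean = 1000, p_pos = 0, mean_pos = 10) {
  name <- match.arg(name)
  stopifnot(shape > 0, mean > 0, p_pos >= 0, p_pos <= 1, mean_pos > 0)
  structure(list(name = name, shape = shape, mean = mean,
                 p_pos = p_pos, mean_pos = mean_pos),
            class = "dfe_model")
}

# Quantile-midpoint discretisation of the deleterious Gamma (returns
# negative S values) and of the beneficial exponential (positive, capped).
gamma_grid <- function(shape, mean, K = 32L) {
  -stats::qgamma((seq_len(K) - 0.5) / K, shape = shape, scale = mean / shape)
}
expo_grid <- function(mean_pos, K = 32L, cap = 500) {
  pmin(stats::qexp((seq_len(K) - 0.5) / K, rate = 1 / mean_pos), cap)
}

# Expected nonsynonymous SFS shape psi_i = E_S[phi_i(S)] under a DFE
# (neutral shape is 1/i).
dfe_expected_shape <- function(model, n, K = 32L, order = 64L) {
  Sg <- gamma_grid(model$shape, model$mean, K)
  phi <- vapply(Sg, function(s) expected_sfs_entry(s, seq_len(n - 1L), n, order), numeric(n - 1L))
  psi <- rowMeans(phi)
  if (model$name == "GammaExpo" && model$p_pos > 0) {
    Sp <- expo_grid(model$mean_pos, K)
    phip <- vapply(Sp, function(s) expected_sfs_entry(s, seq_len(n - 1L), n, order), numeric(n - 1L))
    psi <- (1 - model$p_pos) * psi + model$p_pos * rowMeans(phip)
  }
  psi
}

# Expected dN/dS contributed by the deleterious class of a DFE (relative
# fixation rate integrated over the Gamma, weighted by its class
# probability).
omega_na_of <- function(model, K = 256L) {
  w <- if (model$name == "GammaExpo") 1 - model$p_pos else 1
  w * mean(fixation_factor(gamma_grid(model$shape, model$mean, K)))
}

# Poisson log-likelihood of an SFS pair given theta and a DFE, with r_1 = 1
# and r_i (i >= 2) profiled analytically. Returns loglik and the profiled r.
sfs_loglik <- function(sfs, theta, model, K = 32L, order = 64L) {
  n <- sfs$n
  i <- seq_len(n - 1L)
  a <- theta * sfs$L_syn / i
  b <- theta * sfs$L_nonsyn * dfe_expected_shape(model, n, K, order)
  s <- sfs$syn_sfs; d <- sfs$nonsyn_sfs
  r <- c(1, (s[-1] + d[-1]) / (a[-1] + b[-1]))
  xlog <- function(cnt, mu) ifelse(cnt > 0, cnt * log(mu), 0)
  ll <- sum(xlog(s, r * a) - r * a + xlog(d, r * b) - r * b)
  list(loglik = ll, r = r, a = a, b = b)
}

#' Fit a DFE to a synonymous/nonsynonymous SFS pair
#'
#' Maximises the Poisson likelihood over SFS entries: the synonymous class i
#' has mean `r_i theta L_syn / i`, the nonsynonymous class
#' `r_i theta L_nonsyn psi_i(DFE)`. The nuisance multipliers r_i (r_1 fixed
#' to 1 for identifiability) multiply both spectra and are profiled
#' analytically; theta and the DFE parameters are optimised numerically
#' (quasi-Newton on log/logit scales) with seeded random restarts.
#'
#' @param sfs An `sfs_pair` (see [build_sfs()]).
#' @param model `"GammaZero"` or `"GammaExpo"`, or a [dfe_model()] used as
#'   a starting point.
#' @param n_starts Number of random restarts (first start is deterministic).
#' @param seed Seed for the restarts.
#' @param K,order Discretisation of the DFE integral and quadrature order.
#' @return Object of class `dfe_fit`: `model` (fitted [dfe_model()]),
#'   `theta`, `r`, `loglik`, `convergence` (0 = converged), and the input
#'   `sfs`.
#' @export
fit_dfe <- function(sfs, model = "GammaZero", n_starts = 5L, seed = 1L,
                    K = 32L, order = 64L) {
  if (is.character(model)) model <- dfe_model(model)
  if (sfs$L_syn <= 0 || sfs$L_nonsyn <= 0) stop("SFS must carry positive L_syn and L_nonsyn")
  n <- sfs$n
  expo <- model$name == "GammaExpo"
  theta0 <- max(sum(sfs$syn_sfs) / (sfs$L_syn * sum(1 / seq_len(n - 1L))), 1e-8)
  p0 <- c(log(theta0), log(model$shape), log(model$mean),
          if (expo) c(stats::qlogis(max(model$p_pos, 0.02)), log(model$mean_pos)))
  clamp <- function(z, lo, hi) pmin(pmax(z, lo), hi)
  unpack <- function(par) {
    # soft bounds keep exp() away from under/overflow; the extremes are
    # effectively neutral (mean ~ 1e-5) / lethal (mean ~ 1e6) plateaus
    m <- dfe_model(model$name,
                   shape = exp(clamp(par[2], -7, 3)),
                   mean = exp(clamp(par[3], -11, 14)),
                   p_pos = if (expo) stats::plogis(clamp(par[4], -30, 30)) else 0,
                   mean_pos = if (expo) exp(clamp(par[5], -7, 6.2)) else 10)
    list(theta = exp(clamp(par[1], -35, 10)), model = m)
  }
  negll <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    u <- unpack(par)
    ll <- tryCatch(sfs_loglik(sfs, u$theta, u$model, K, order)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- list(p0)
  boundary <- NULL
  if (expo) {
    # nested GammaZero optimum: both a warm start and, with a vanishing
    # positive class, a boundary candidate -- the optimizer approaches
    # p_pos = 0 only logarithmically, so the boundary is checked directly
    # to guarantee the nesting inequality
    f0 <- fit_dfe(sfs, dfe_model("GammaZero", shape = model$shape, mean = model$mean),
                  n_starts = max(2L, n_starts - 2L), seed = seed, K = K, order = order)
    boundary <- c(log(f0$theta), log(f0$model$shape), log(f0$model$mean),
                  stats::qlogis(1e-12), log(model$mean_pos))
    starts <- c(starts, list(c(boundary[1:3], stats::qlogis(1e-4), log(model$mean_pos))))
  }
  best <- NULL
  for (k in seq_len(n_starts + length(starts) - 1L)) {
    start <- if (k <= length(starts)) starts[[k]] else p0 + stats::rnorm(length(p0), 0, 1)
    opt <- tryCatch(stats::optim(start, negll, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.null(boundary)) {
    vb <- negll(boundary)
    if (is.null(best) || vb < best$value)
      best <- list(par = boundary, value = vb, convergence = 0L)
  }
  if (is.null(best)) stop("DFE optimisation failed from every start")
  u <- unpack(best$par)
  prof <- sfs_loglik(sfs, u$theta, u$model, K, order)
  structure(list(model = u$model, theta = u$theta, r = prof$r,
                 loglik = -best$value, convergence = best$convergence,
                 K = K, order = order, sfs = sfs),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("dfe_fit %s: shape=%.3g mean|S|=%.4g%s theta=%.3g loglik=%.3f%s\n",
              x$model$name, x$model$shape, x$model$mean,
              if (x$model$name == "GammaExpo")
                sprintf(" p_pos=%.3g meanS+=%.3g", x$model$p_pos, x$model$mean_pos) else "",
              x$theta, x$loglik,
              if (x$convergence != 0) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Adaptive and nonadaptive substitution rates from a DFE fit
#'
#' `omega_na` is the dN/dS expected under the fitted deleterious DFE (the
#' Gamma-integrated relative fixation rate `S/(1-exp(-S))`); `alpha = 1 -
#' omega_na / (dN/dS)` and `omega_a = alpha * (dN/dS)`, with the observed
#' dN/dS computed from the divergence counts of the same gene set and
#' category as the SFS.
#'
#' @param fit A `dfe_fit`.
#' @param D_syn,D_nonsyn,L_syn,L_nonsyn Divergence counts and site totals;
#'   default: the values carried by the fitted SFS.
#' @return List with `alpha`, `omega_a`, `omega_na`, `dnds_obs`.
#' @export
alpha_omega <- function(fit, D_syn = fit$sfs$D_syn, D_nonsyn = fit$sfs$D_nonsyn,
                        L_syn = fit$sfs$L_syn, L_nonsyn = fit$sfs$L_nonsyn) {
  if (is.na(D_syn) || D_syn <= 0) stop("D_syn must be positive")
  dnds <- (D_nonsyn / L_nonsyn) / (D_syn / L_syn)
  omega_na <- omega_na_of(fit$model)
  if (dnds == 0) return(list(alpha = NA_real_, omega_a = NA_real_,
                             omega_na = omega_na, dnds_obs = 0))
  alpha <- 1 - omega_na / dnds
  list(alpha = alpha, omega_a = alpha * dnds, omega_na = omega_na, dnds_obs = dnds)
}

# Constrained refit: maximise the likelihood subject to the deleterious
# omega_na equalling a target, by solving the Gamma mean from (shape, p_pos)
# along the profile. Returns the profile log-likelihood (-Inf when the
# constraint is unattainable).
profile_loglik_at <- function(fit, omega_na0) {
  sfs <- fit$sfs
  expo <- fit$model$name == "GammaExpo"
  solve_mean <- function(shape, w) {
    # E[f] over Gamma(shape, mean) is 1 at mean -> 0 and -> 0 as mean grows
    target <- omega_na0 / w
    if (target <= 0 || target >= 1) return(NA_real_)
    g <- function(lm) mean(fixation_factor(gamma_grid(shape, exp(lm), 256L))) - target
    lo <- -12; hi <- 16
    if (g(lo) < 0 || g(hi) > 0) return(NA_real_)
    exp(stats::uniroot(g, c(lo, hi), tol = 1e-9)$root)
  }
  clamp <- function(z, lo, hi) pmin(pmax(z, lo), hi)
  negll <- function(par) {
    if (any(!is.finite(par))) return(1e12)
    p_pos <- if (expo) stats::plogis(clamp(par[3], -30, 30)) else 0
    w <- 1 - p_pos
    shape <- exp(clamp(par[2], -7, 3))
    mean_del <- solve_mean(shape, w)
    if (is.na(mean_del)) return(1e12)
    m <- dfe_model(fit$model$name, shape = shape, mean = mean_del,
                   p_pos = p_pos, mean_pos = if (expo) exp(clamp(par[4], -7, 6.2)) else 10)
    ll <- tryCatch(sfs_loglik(sfs, exp(clamp(par[1], -35, 10)), m, fit$K, fit$order)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  start <- c(log(fit$theta), log(fit$model$shape),
             if (expo) c(stats::qlogis(max(fit$model$p_pos, 1e-3)), log(fit$model$mean_pos)))
  opt <- tryCatch(stats::optim(start, negll, method = "BFGS",
                               control = list(maxit = 300, reltol = 1e-9)),
                  error = function(e) NULL)
  if (is.null(opt) || opt$value >= 1e11) -Inf else -opt$value
}

#' Likelihood-profile confidence interval for alpha or omega_a
#'
#' Bounds are the values of the target for which the profile log-likelihood
#' (re-optimising theta and the remaining DFE parameters, with the Gamma
#' mean constrained so the model's omega_na matches the target) drops
#' `delta` units below the maximum (default 2, the convention used with
#' this estimator family).
#'
#' @param fit A `dfe_fit`.
#' @param target `"alpha"` or `"omega_a"`.
#' @param delta Log-likelihood drop defining the interval (default 2).
#' @param D_syn,D_nonsyn,L_syn,L_nonsyn Divergence inputs as in
#'   [alpha_omega()].
#' @return List with `low`, `high`, `point`, and logical flags
#'   `low_open`/`high_open` when a bound hit the parameter-space limit
#'   (one-sided interval).
#' @export
profile_ci <- function(fit, target = c("alpha", "omega_a"), delta = 2,
                       D_syn = fit$sfs$D_syn, D_nonsyn = fit$sfs$D_nonsyn,
                       L_syn = fit$sfs$L_syn, L_nonsyn = fit$sfs$L_nonsyn) {
  target <- match.arg(target)
  ao <- alpha_omega(fit, D_syn, D_nonsyn, L_syn, L_nonsyn)
  dnds <- ao$dnds_obs
  point <- if (target == "alpha") ao$alpha else ao$omega_a
  to_omega_na <- function(v) if (target == "alpha") (1 - v) * dnds else dnds - v
  llmax <- fit$loglik
  ll_at <- function(v) profile_loglik_at(fit, to_omega_na(v))
  crossing <- function(dir) {
    step <- if (target == "alpha") 0.05 else max(0.05 * abs(dnds), 1e-4)
    v <- point; lastv <- point
    for (k in 1:60) {
      v <- v + dir * step
      # omega_na must stay in (0, ~1): alpha bounded above by 1 (omega_na > 0)
      w0 <- to_omega_na(v)
      if (w0 <= 1e-9)  # alpha -> 1 / omega_a -> dN/dS limit of the parameter space
        return(list(bound = if (target == "alpha") min(v, 1) else min(v, dnds), open = TRUE))
      llv <- ll_at(v)
      if (!is.finite(llv) || llmax - llv > delta) {
        f <- function(u) (llmax - ll_at(u)) - delta
        r <- tryCatch(stats::uniroot(f, c(lastv, v), tol = 1e-4)$root,
                      error = function(e) v)
        return(list(bound = r, open = FALSE))
      }
      lastv <- v
      step <- step * 1.6
    }
    list(bound = v, open = TRUE)
  }
  up <- crossing(+1)
  dn <- crossing(-1)
  list(low = dn$bound, high = up$bound, point = point,
       low_open = dn$open, high_open = up$open)
}
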