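# Bayesian 2 x 3 repeated-measures inference: normal linear model with
# speed, amplitude and their interaction as fixed effects and a subject
# random intercept. Fixed-effect (difference) coefficients carry a
# N(0, (1.6 * sigma)^2) prior, i.e. N(0, 1.6^2) on the standardized
# effect; variance components carry half-Cauchy priors. Sampling is
# Gibbs for the conditionally conjugate blocks (coefficients, subject
# intercepts) and log-scale random-walk Metropolis for the two standard
# deviations.

model_matrix_2x3 <- function(speed, amplitude) {
  speed <- factor(speed, levels = c("normal", "slow"))
  amplitude <- factor(amplitude, levels = sort(unique(as.numeric(as.character(amplitude)))))
  amps <- levels(amplitude)
  s <- as.integer(speed == "slow")
  X <- cbind(`(Intercept)` = 1, speed_slow = s)
  for (a in amps[-1L]) X <- cbind(X, as.integer(amplitude == a))
  colnames(X)[2L + seq_along(amps[-1L])] <- paste0("amp_", amps[-1L])
  for (a in amps[-1L]) X <- cbind(X, s * as.integer(amplitude == a))
  colnames(X)[(1L + length(amps)) + seq_along(amps[-1L])] <-
    paste0("speed_slow:amp_", amps[-1L])
  X
}

half_cauchy_log <- function(x, scale) dcauchy(x, 0, scale, log = TRUE) + log(2)

#' Fit the Bayesian repeated-measures model
#'
#' `value ~ speed * amplitude + (1 | subject)` with Gaussian residuals.
#' Difference-coded fixed effects (slow vs normal; each amplitude vs
#' the first; their interactions) have conditional priors
#' `N(0, (prior_scale * sigma)^2)`, so a standardized contrast
#' `c'beta / sigma` has the scale-free prior `N(0, (prior_scale *
#' ||c||)^2)`; the intercept prior is vague. Residual and
#' subject-intercept SDs have half-Cauchy(0, `var_prior_scale * sd(y)`)
#' priors.
#'
#' @param data data.frame with columns `subject`, `speed`
#'   (normal/slow), `amplitude` and the response.
#' @param response name of the response column.
#' @param chains number of MCMC chains (>= 2 recommended).
#' @param iter post-warmup iterations per chain.
#' @param warmup warmup iterations per chain (discarded).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior_scale prior SD of standardized effects (default 1.6,
#'   which puts about 80% prior mass on effect sizes between -2 and 2).
#' @param var_prior_scale half-Cauchy scale multiplier for the SDs.
#' @return object of class `turn_effects_fit`; see [summary.turn_effects_fit()],
#'   [effect_estimates()], [cohens_d()], [eta_squared()].
#' @export
fit_turn_effects <- function(data, response = "value", chains = 2L,
                             iter = 2000L, warmup = 500L, seed = 1L,
                             prior_scale = 1.6, var_prior_scale = 2.5) {
  stopifnot(all(c("subject", "speed", "amplitude", response) %in% colnames(data)))
  y <- as.numeric(data[[response]])
  ok <- !is.na(y)
  y <- y[ok]
  X <- model_matrix_2x3(data$speed[ok], data$amplitude[ok])
  subj <- factor(data$subject[ok])
  ns <- nlevels(subj)
  si <- as.integer(subj)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L) stop("too few observations for the 2 x 3 model")
  sy <- max(sd(y), 1e-8)
  g <- prior_scale
  hc_scale <- var_prior_scale * sy
  int_prior_var <- (10 * sy + abs(mean(y)))^2
  XtX <- crossprod(X)

  beta_init <- tryCatch(qr.solve(XtX, crossprod(X, y)),
                        error = function(e) matrix(0, p, 1L))
  resid0 <- y - X %*% beta_init
  sig_init <- max(sd(resid0), 1e-6 * sy, 1e-10)

  run_chain <- function(chain_id) {
    set.seed(seed + chain_id - 1L)
    beta <- as.numeric(beta_init)
    b <- rep(0, ns)
    sigma <- sig_init
    sigma_b <- max(0.3 * sy, 1e-10)
    total <- warmup + iter
    keep <- matrix(NA_real_, iter, p + 2L + ns)
    colnames(keep) <- c(colnames(X), "sigma", "sigma_b",
                        paste0("b_", levels(subj)))
    acc <- c(sigma = 0L, sigma_b = 0L)
    step <- 0.35
    ns_count <- tabulate(si, ns)
    for (it in seq_len(total)) {
      ## beta | rest (conjugate)
      ystar <- y - b[si]
      Dprec <- c(1 / int_prior_var, rep(1 / (g^2 * sigma^2), p - 1L))
      A <- XtX / sigma^2 + diag(Dprec, p)
      ch <- chol(A)
      mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, ystar) / sigma^2))
      beta <- as.numeric(mu + backsolve(ch, rnorm(p)))
      ## subject intercepts | rest (conjugate)
      r <- y - as.numeric(X %*% beta)
      sums <- tapply(r, si, sum)
      prec <- ns_count / sigma^2 + 1 / sigma_b^2
      bmean <- (as.numeric(sums) / sigma^2) / prec
      b <- rnorm(ns, bmean, sqrt(1 / prec))
      ## sigma | rest (Metropolis on log scale; prior of beta depends on it)
      resid <- r - b[si]
      logpost_sig <- function(s) {
        sum(dnorm(resid, 0, s, log = TRUE)) +
          sum(dnorm(beta[-1L], 0, g * s, log = TRUE)) +
          half_cauchy_log(s, hc_scale) + log(s)
      }
      prop <- sigma * exp(rnorm(1, 0, step))
      if (is.finite(prop) && prop > 1e-12 &&
          log(runif(1)) < logpost_sig(prop) - logpost_sig(sigma)) {
        sigma <- prop; acc["sigma"] <- acc["sigma"] + 1L
      }
      ## sigma_b | rest
      logpost_sb <- function(s) {
        sum(dnorm(b, 0, s, log = TRUE)) + half_cauchy_log(s, hc_scale) + log(s)
      }
      prop <- sigma_b * exp(rnorm(1, 0, step))
      if (is.finite(prop) && prop > 1e-12 &&
          log(runif(1)) < logpost_sb(prop) - logpost_sb(sigma_b)) {
        sigma_b <- prop; acc["sigma_b"] <- acc["sigma_b"] + 1L
      }
      if (it > warmup) keep[it - warmup, ] <- c(beta, sigma, sigma_b, b)
    }
    list(samples = keep, accept = acc / total)
  }

  chains_out <- lapply(seq_len(chains), run_chain)
  sample_list <- lapply(chains_out, `[[`, "samples")
  combined <- do.call(rbind, sample_list)
  diag_par <- c(colnames(X), "sigma", "sigma_b")
  diags <- mcmc_diagnostics(sample_list, parameters = diag_par)
  converged <- all(is.finite(diags$rhat)) && all(diags$rhat < 1.01)
  if (!converged)
    warning(sprintf("MCMC not converged: max split-Rhat = %.3f (increase iter)",
                    max(diags$rhat, na.rm = TRUE)))
  if (any(diags$ess < 10000))
    message(sprintf(
      "note: smallest effective sample size %.0f is below 10,000; lengthen the chains for reporting",
      min(diags$ess)))
  structure(list(chains = sample_list, samples = combined,
                 coef_names = colnames(X), subject_levels = levels(subj),
                 amplitude_levels = levels(factor(as.numeric(as.character(data$amplitude[ok])))),
                 data = data.frame(subject = subj, speed = data$speed[ok],
                                   amplitude = data$amplitude[ok], y = y),
                 response = response, prior_scale = g,
                 hc_scale = hc_scale, seed = seed,
                 accept = lapply(chains_out, `[[`, "accept"),
                 diagnostics = diags, converged = converged),
            class = "turn_effects_fit")
}

#' Named contrast vectors on the fixed effects
#'
#' Rows are contrasts of cell means expressed on the difference-coded
#' coefficients: the slow-minus-normal difference at each amplitude,
#' pairwise amplitude differences within each speed, and the speed main
#' effect averaged over amplitudes.
#'
#' @param fit a `turn_effects_fit`.
#' @return numeric matrix, one named row per contrast, columns matching
#'   `coef(fit)`.
#' @export
turn_contrasts <- function(fit) {
  cn <- fit$coef_names
  p <- length(cn)
  amps <- fit$amplitude_levels
  unit <- function(names_on) {
    v <- setNames(numeric(p), cn)
    for (nm in names(names_on)) v[nm] <- names_on[[nm]]
    v
  }
  rows <- list()
  rows[[paste0("speed_slow_minus_normal@", amps[1L])]] <- unit(list(speed_slow = 1))
  for (a in amps[-1L]) {
    rows[[paste0("speed_slow_minus_normal@", a)]] <-
      unit(setNames(list(1, 1), c("speed_slow", paste0("speed_slow:amp_", a))))
  }
  for (sp in if (length(amps) >= 2L) c("normal", "slow") else character(0)) {
    for (i in 2L:length(amps)) {
      for (j in seq_len(i - 1L)) {
        nm <- paste0("amp_", amps[i], "_minus_", amps[j], "@", sp)
        w <- list()
        w[[paste0("amp_", amps[i])]] <- 1
        if (j > 1L) w[[paste0("amp_", amps[j])]] <- -1
        if (sp == "slow") {
          w[[paste0("speed_slow:amp_", amps[i])]] <- 1
          if (j > 1L) {
            key <- paste0("speed_slow:amp_", amps[j])
            w[[key]] <- if (is.null(w[[key]])) -1 else w[[key]] - 1
          }
        }
        rows[[nm]] <- unit(w)
      }
    }
  }
  main <- unit(list(speed_slow = 1))
  for (a in amps[-1L])
    main[paste0("speed_slow:amp_", a)] <- 1 / length(amps)
  rows[["speed_main"]] <- main
  do.call(rbind, rows)
}

#' Posterior samples of a contrast (raw response units)
#'
#' @param fit a `turn_effects_fit`.
#' @param contrast contrast name from [turn_contrasts()] or a numeric
#'   vector on the coefficients.
#' @return numeric vector of posterior draws of `c'beta`.
#' @export
contrast_samples <- function(fit, contrast) {
  cm <- resolve_contrast(fit, contrast)
  as.numeric(fit$samples[, fit$coef_names, drop = FALSE] %*% cm)
}

resolve_contrast <- function(fit, contrast) {
  if (is.character(contrast)) {
    tc <- turn_contrasts(fit)
    if (!contrast %in% rownames(tc))
      stop(sprintf("unknown contrast '%s'; see turn_contrasts()", contrast))
    tc[contrast, ]
  } else {
    stopifnot(length(contrast) == length(fit$coef_names))
    setNames(as.numeric(contrast), fit$coef_names)
  }
}

#' Posterior Cohen's d of a contrast
#'
#' Standardized samplewise: `d = c'beta / sigma` (residual SD), so it is
#' invariant to the response scale.
#'
#' @inheritParams contrast_samples
#' @return numeric vector of posterior d draws.
#' @export
cohens_d <- function(fit, contrast) {
  contrast_samples(fit, contrast) / fit$samples[, "sigma"]
}

#' Highest-density interval
#'
#' Shortest interval containing `mass` of the sample: the minimal
#' `ceiling(mass * n)`-wide window of the sorted draws.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass probability mass (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  x <- sort(samples[!is.na(samples)])
  n <- length(x)
  if (!n) stop("hdi: no samples")
  m <- min(n, max(1L, as.integer(ceiling(mass * n))))
  if (m == n) return(c(low = x[1L], high = x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(low = x[i], high = x[i + m])
}

#' ROPE half-width from the pooled data
#'
#' A small effect -- 0.2 standard deviations of all subject-condition
#' values of the parameter -- defines the region of practical
#' equivalence.
#'
#' @param values all subject-condition values of the parameter.
#' @param small effect-size multiple (default 0.2).
#' @return half-width in raw units.
#' @export
rope_halfwidth <- function(values, small = 0.2) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("rope_halfwidth needs at least 2 values")
  small * sd(v)
}

#' HDI+ROPE decision
#'
#' `different` when the 95% HDI and the ROPE are disjoint,
#' `practically_equivalent` when the HDI lies inside the ROPE,
#' `undecided` otherwise.
#'
#' @param samples posterior draws of the effect.
#' @param halfwidth ROPE half-width (same units as the samples).
#' @param mass HDI mass.
#' @return list with `pct_in_rope` (percent of draws inside the ROPE),
#'   `hdi`, and `decision`.
#' @export
rope_decision <- function(samples, halfwidth, mass = 0.95) {
  stopifnot(halfwidth >= 0)
  h <- hdi(samples, mass)
  decision <- if (h[["low"]] > halfwidth || h[["high"]] < -halfwidth) {
    "different"
  } else if (h[["low"]] >= -halfwidth && h[["high"]] <= halfwidth) {
    "practically_equivalent"
  } else {
    "undecided"
  }
  list(pct_in_rope = 100 * mean(abs(samples) <= halfwidth),
       hdi = h, decision = decision)
}

density_at <- function(samples, at) {
  d <- density(samples, bw = "nrd0")  # Silverman's rule
  if (at < min(d$x) || at > max(d$x)) return(0)
  approx(d$x, d$y, xout = at)$y
}

#' Savage-Dickey Bayes factor
#'
#' For a nested point null at 0: `BF01` is the ratio of the posterior
#' to the prior density at 0 (kernel density estimate with Silverman's
#' bandwidth); `BF10 = 1 / BF01`.
#'
#' @param samples posterior draws of the (standardized) effect.
#' @param prior_sd SD of the normal prior at that scale (the
#'   standardized-effect prior is N(0, 1.6)).
#' @param prior_mean prior mean (default 0).
#' @return list with `bf10`, `bf01`, `posterior_density_0`,
#'   `prior_density_0`.
#' @export
bayes_factor_savage_dickey <- function(samples, prior_sd = 1.6, prior_mean = 0) {
  post0 <- density_at(samples, 0)
  prior0 <- dnorm(0, prior_mean, prior_sd)
  bf01 <- post0 / prior0
  list(bf10 = if (bf01 > 0) 1 / bf01 else Inf, bf01 = bf01,
       posterior_density_0 = post0, prior_density_0 = prior0)
}

#' Bayes-factor robustness over prior widths
#'
#' @param samples posterior draws of the standardized effect.
#' @param prior_sds grid of prior SDs.
#' @return data.frame with `prior_sd`, `bf10`, `bf01`.
#' @export
bf_robustness <- function(samples, prior_sds = c(0.5, 1, 1.6, 2.5, 5)) {
  rows <- lapply(prior_sds, function(s) {
    bf <- bayes_factor_savage_dickey(samples, prior_sd = s)
    data.frame(prior_sd = s, bf10 = bf$bf10, bf01 = bf$bf01)
  })
  do.call(rbind, rows)
}

#' MAP-based p-value
#'
#' Ratio of the posterior density at 0 to the density at the posterior
#' mode, clipped to [0, 1]: 1 when the mode is at the null, near 0 when
#' the posterior is far from it.
#'
#' @param samples posterior draws.
#' @return numeric in [0, 1].
#' @export
p_map <- function(samples) {
  d <- density(samples, bw = "nrd0")
  at0 <- if (0 < min(d$x) || 0 > max(d$x)) 0 else approx(d$x, d$y, xout = 0)$y
  min(1, at0 / max(d$y))
}

#' Split-Rhat and effective sample size
#'
#' Split-Rhat (each chain halved, between/within variance ratio) and an
#' autocorrelation-based effective sample size with Geyer initial
#' positive-sequence truncation, computed per parameter.
#'
#' @param chains list of iteration x parameter matrices (one per
#'   chain), or a single matrix/vector (treated as one chain).
#' @param parameters optional subset of parameter names.
#' @return list with named vectors `rhat` and `ess`.
#' @export
mcmc_diagnostics <- function(chains, parameters = NULL) {
  if (!is.list(chains)) {
    chains <- list(if (is.matrix(chains)) chains else matrix(chains, ncol = 1L,
                                                             dimnames = list(NULL, "par")))
  }
  cn <- colnames(chains[[1L]])
  if (is.null(cn)) cn <- paste0("par", seq_len(ncol(chains[[1L]])))
  chains <- lapply(chains, function(m) {
    m <- as.matrix(m); colnames(m) <- cn; m
  })
  if (!is.null(parameters)) cn <- intersect(cn, parameters)
  rhat <- setNames(numeric(length(cn)), cn)
  ess <- setNames(numeric(length(cn)), cn)
  for (p in cn) {
    draws <- lapply(chains, function(m) m[, p])
    rhat[p] <- split_rhat_one(draws)
    ess[p] <- ess_one(draws)
  }
  list(rhat = rhat, ess = ess)
}

split_rhat_one <- function(draws) {
  half <- lapply(draws, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[(length(x) - n2 + 1L):length(x)])
  })
  parts <- unlist(half, recursive = FALSE)
  n <- min(lengths(parts))
  if (n < 2L) return(NA_real_)
  parts <- lapply(parts, function(x) x[seq_len(n)])
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(draws) {
  m <- length(draws)
  n <- min(lengths(draws))
  draws <- lapply(draws, function(x) x[seq_len(n)])
  vars <- vapply(draws, var, numeric(1))
  means <- vapply(draws, mean, numeric(1))
  W <- mean(vars)
  var_plus <- (n - 1) / n * W + (if (m > 1L) var(means) else 0)
  if (!is.finite(var_plus) || var_plus <= 0) return(m * n)
  acov <- vapply(draws, function(x) {
    a <- stats::acf(x, lag.max = min(n - 1L, 10000L), type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
    a
  }, numeric(min(n - 1L, 10000L) + 1L))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1L] <- 1
  # Geyer: sum consecutive pairs, stop at the first negative pair,
  # enforce monotone nonincreasing pair sums.
  maxpair <- floor((length(rho) - 1L) / 2)
  tau <- 0
  prev <- Inf
  if (maxpair >= 1L) {
    for (k in seq_len(maxpair)) {
      pk <- rho[2 * k] + rho[2 * k + 1L]
      if (!is.finite(pk) || pk <= 0) break
      pk <- min(pk, prev)
      tau <- tau + pk
      prev <- pk
    }
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Posterior eta squared of a factor
#'
#' Variance-fraction effect size computed samplewise from the posterior
#' cell means of the balanced 2 x 3 design: the factor's
#' sum of squares over the cells divided by the systematic sums of
#' squares plus the residual and subject variance contribution
#' (`6 * (sigma^2 + sigma_b^2)`), so values lie in [0, 1] and a null
#' simulation concentrates near 0.
#'
#' @param fit a `turn_effects_fit`.
#' @param factor `"speed"`, `"amplitude"` or `"interaction"`.
#' @return numeric vector of posterior eta-squared draws.
#' @export
eta_squared <- function(fit, factor = c("speed", "amplitude", "interaction")) {
  factor <- match.arg(factor)
  amps <- fit$amplitude_levels
  na <- length(amps)
  grid <- expand.grid(speed = c("normal", "slow"), amplitude = amps,
                      stringsAsFactors = FALSE)
  Xc <- model_matrix_2x3(grid$speed, grid$amplitude)
  cells <- fit$samples[, fit$coef_names, drop = FALSE] %*% t(Xc)  # draws x 6
  sig2 <- fit$samples[, "sigma"]^2 + fit$samples[, "sigma_b"]^2
  sp <- grid$speed
  am <- grid$amplitude
  n_draw <- nrow(cells)
  grand <- rowMeans(cells)
  rmean <- sapply(c("normal", "slow"), function(s) rowMeans(cells[, sp == s, drop = FALSE]))
  cmean <- sapply(amps, function(a) rowMeans(cells[, am == a, drop = FALSE]))
  ss_speed <- na * rowSums((rmean - grand)^2)
  ss_amp <- 2 * rowSums((cmean - grand)^2)
  resmat <- cells
  for (j in seq_len(ncol(cells))) {
    resmat[, j] <- cells[, j] - rmean[, sp[j]] - cmean[, am[j]] + grand
  }
  ss_int <- rowSums(resmat^2)
  total <- ss_speed + ss_amp + ss_int + 2 * na * sig2
  ss_f <- switch(factor, speed = ss_speed, amplitude = ss_amp,
                 interaction = ss_int)
  pmin(1, pmax(0, ss_f / total))
}

#' Effect estimates with HDI+ROPE decisions
#'
#' One row per contrast: posterior mean difference and 95% HDI in raw
#' units, Cohen's d posterior summary, Savage-Dickey BF10 on the
#' standardized scale, MAP-based p-value, percent of the posterior in
#' the ROPE and the three-way HDI+ROPE decision, with a decision glyph
#' (`>`/`<` different, `=` practically equivalent, `?` undecided).
#'
#' @param fit a `turn_effects_fit`.
#' @param rope half-width of the ROPE in raw response units; by default
#'   0.2 SD of the response values in the fit.
#' @param contrasts character vector of contrast names (default: all of
#'   [turn_contrasts()]).
#' @param mass HDI mass.
#' @return data.frame of class `turn_effect_table`.
#' @export
effect_estimates <- function(fit, rope = NULL, contrasts = NULL, mass = 0.95) {
  tc <- turn_contrasts(fit)
  if (is.null(contrasts)) contrasts <- rownames(tc)
  if (is.null(rope)) rope <- rope_halfwidth(fit$data$y)
  rows <- lapply(contrasts, function(nm) {
    delta <- contrast_samples(fit, nm)
    d <- cohens_d(fit, nm)
    ceff <- tc[nm, setdiff(fit$coef_names, "(Intercept)")]
    prior_sd <- fit$prior_scale * sqrt(sum(ceff^2))
    bf <- bayes_factor_savage_dickey(d, prior_sd = prior_sd)
    rd <- rope_decision(delta, rope, mass)
    dh <- hdi(d, mass)
    glyph <- switch(rd$decision,
                    different = if (mean(delta) > 0) ">" else "<",
                    practically_equivalent = "=", undecided = "?")
    data.frame(contrast = nm, estimate = mean(delta),
               hdi_low = rd$hdi[["low"]], hdi_high = rd$hdi[["high"]],
               d = mean(d), d_hdi_low = dh[["low"]], d_hdi_high = dh[["high"]],
               bf10 = bf$bf10, p_map = p_map(d),
               rope_halfwidth = rope, pct_in_rope = rd$pct_in_rope,
               decision = rd$decision, glyph = glyph,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("turn_effect_table", "data.frame")
  out
}
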