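# S3 methods for the fitted Bayesian model.

#' @export
print.turn_effects_fit <- function(x, ...) {
  cat(sprintf("<turn_effects_fit> response '%s': %d obs, %d subjects, %d chains x %d draws\n",
              x$response, nrow(x$data), length(x$subject_levels),
              length(x$chains), nrow(x$chains[[1L]])))
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f%s\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object a `turn_effects_fit`.
#' @param ... unused.
#' @return named numeric vector (difference-coded fixed effects).
#' @export
coef.turn_effects_fit <- function(object, ...) {
  colMeans(object$samples[, object$coef_names, drop = FALSE])
}

#' Summarize a fitted turn-effects model
#'
#' @param object a `turn_effects_fit`.
#' @param rope ROPE half-width (raw units); default 0.2 SD of the data.
#' @param ... passed to [effect_estimates()].
#' @return list with `effects` (a `turn_effect_table`), `eta_squared`
#'   posterior means, and `diagnostics`.
#' @export
summary.turn_effects_fit <- function(object, rope = NULL, ...) {
  eff <- effect_estimates(object, rope = rope, ...)
  es <- c(speed = mean(eta_squared(object, "speed")),
          amplitude = mean(eta_squared(object, "amplitude")),
          interaction = mean(eta_squared(object, "interaction")))
  out <- list(effects = eff, eta_squared = es,
              diagnostics = object$diagnostics, response = object$response)
  class(out) <- "summary.turn_effects_fit"
  out
}

#' @export
print.summary.turn_effects_fit <- function(x, ...) {
  cat(sprintf("Bayesian 2 x 3 repeated-measures effects for '%s'\n", x$response))
  eff <- x$effects
  eff$estimate <- signif(eff$estimate, 4)
  eff$hdi_low <- signif(eff$hdi_low, 4)
  eff$hdi_high <- signif(eff$hdi_high, 4)
  eff$d <- signif(eff$d, 3)
  eff$bf10 <- signif(eff$bf10, 3)
  eff$pct_in_rope <- round(eff$pct_in_rope, 1)
  print.data.frame(eff[, c("contrast", "estimate", "hdi_low", "hdi_high",
                           "d", "bf10", "pct_in_rope", "glyph")],
                   row.names = FALSE)
  cat(sprintf("eta^2: speed %.3f, amplitude %.3f, interaction %.3f\n",
              x$eta_squared[["speed"]], x$eta_squared[["amplitude"]],
              x$eta_squared[["interaction"]]))
  cat(sprintf("max split-Rhat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Posterior-mean fitted values
#'
#' @param object a `turn_effects_fit`.
#' @param newdata optional data.frame with `speed` and `amplitude`
#'   columns (subject intercepts are not added for new data).
#' @param ... unused.
#' @return numeric vector of fitted cell means.
#' @export
predict.turn_effects_fit <- function(object, newdata = NULL, ...) {
  beta <- coef(object)
  if (is.null(newdata)) {
    X <- model_matrix_2x3(object$data$speed, object$data$amplitude)
    b <- colMeans(object$samples[, paste0("b_", object$subject_levels), drop = FALSE])
    as.numeric(X %*% beta) + b[as.integer(object$data$subject)]
  } else {
    X <- model_matrix_2x3(newdata$speed, newdata$amplitude)
    as.numeric(X %*% beta)
  }
}

#' @export
residuals.turn_effects_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' Simulate from the posterior predictive
#'
#' Each simulation draws one posterior sample of the coefficients,
#' subject intercepts and residual SD and generates a response vector
#' for the observed design.
#'
#' @param object a `turn_effects_fit`.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.turn_effects_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- model_matrix_2x3(object$data$speed, object$data$amplitude)
  si <- as.integer(object$data$subject)
  draws <- sample.int(nrow(object$samples), nsim, replace = TRUE)
  out <- sapply(draws, function(i) {
    beta <- object$samples[i, object$coef_names]
    b <- object$samples[i, paste0("b_", object$subject_levels)]
    mu <- as.numeric(X %*% beta) + b[si]
    rnorm(length(mu), mu, object$samples[i, "sigma"])
  })
  as.data.frame(out)
}

#' Plot posterior contrasts against the ROPE
#'
#' Kernel-density estimates of the raw contrast posteriors with the
#' region of practical equivalence shaded.
#'
#' @param x a `turn_effects_fit`.
#' @param contrasts contrast names (default: the per-amplitude speed
#'   contrasts).
#' @param rope ROPE half-width; default 0.2 SD of the data.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.turn_effects_fit <- function(x, contrasts = NULL, rope = NULL, ...) {
  if (is.null(rope)) rope <- rope_halfwidth(x$data$y)
  if (is.null(contrasts)) {
    tc <- rownames(turn_contrasts(x))
    contrasts <- grep("^speed_slow_minus_normal@", tc, value = TRUE)
  }
  old <- par(mfrow = c(length(contrasts), 1), mar = c(3.5, 3.5, 2, 1),
             mgp = c(2.2, 0.7, 0))
  on.exit(par(old))
  for (nm in contrasts) {
    delta <- contrast_samples(x, nm)
    d <- density(delta)
    plot(d, main = nm, xlab = sprintf("contrast (%s units)", x$response),
         ylab = "posterior density")
    polygon(c(-rope, rope, rope, -rope), c(0, 0, max(d$y), max(d$y)),
            col = adjustcolor("grey", 0.4), border = NA)
    lines(d)
    abline(v = 0, lty = 2)
  }
  invisible(x)
}

#' Plot a trial analysis
#'
#' Footfall positions (internal/external legs) over the pelvis path,
#' with the analysis window marked on a yaw-rate inset.
#'
#' @param x a `turn_analysis` from [analyze_trial()].
#' @param recording the analyzed [trial_recording()] (for the pelvis
#'   path); optional.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.turn_analysis <- function(x, recording = NULL, ...) {
  old <- par(mfrow = c(2, 1), mar = c(3.5, 3.5, 2, 1), mgp = c(2.2, 0.7, 0))
  on.exit(par(old))
  ev <- x$events
  seg <- x$segment
  if (!is.null(recording)) {
    ctr <- (marker(recording, "LASI") + marker(recording, "RASI") +
              marker(recording, "LPSI") + marker(recording, "RPSI")) / 4
    plot(ctr[, 1L], ctr[, 2L], type = "l", col = "grey40", asp = 1,
         xlab = "x (m)", ylab = "y (m)", main = "pelvis path and footfalls")
    hs <- hs_table(recording, ev)
    cols <- ifelse(hs$side == seg$internal_side, "tomato", "steelblue")
    points(hs$x, hs$y, pch = 19, col = cols)
    legend("topleft", bty = "n", pch = 19, col = c("tomato", "steelblue"),
           legend = c("internal leg", "external leg"))
  } else {
    plot.new(); title("pelvis path (recording not supplied)")
  }
  plot(x$yaw$time, x$yaw$rate, type = "l", xlab = "time (s)",
       ylab = "yaw rate (deg/s)", main = "turn segmentation")
  abline(h = c(-seg$threshold, seg$threshold), lty = 3)
  abline(v = c(seg$yaw_onset_time, seg$yaw_offset_time), col = "tomato")
  abline(v = c(seg$window_start_time, seg$window_end_time), col = "steelblue",
         lty = 2)
  invisible(x)
}
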