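#' Observed two-population trajectory data
#'
#' Container for a time course of non-Treg (`x_obs`) and Treg (`y_obs`)
#' abundances, observed or synthetic.
#'
#' @param times strictly increasing time grid (hours).
#' @param x_obs,y_obs non-negative abundances, same length as `times`.
#' @param noise_sd observation-noise scale (log-scale SD) used to generate
#'   the data, if known; `NA` for real data.
#' @return an object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(times, x_obs, y_obs, noise_sd = NA_real_) {
  check_time_grid(times)
  if (length(x_obs) != length(times) || length(y_obs) != length(times))
    stop("times, x_obs and y_obs must have equal length", call. = FALSE)
  if (any(!is.finite(x_obs)) || any(!is.finite(y_obs)) ||
      any(x_obs < 0) || any(y_obs < 0))
    stop("observed abundances must be finite and non-negative", call. = FALSE)
  structure(list(times = as.numeric(times), x_obs = as.numeric(x_obs),
                 y_obs = as.numeric(y_obs), noise_sd = noise_sd),
            class = "trajectory_dataset")
}

# Free parameters estimated per model. g_y is fixed at 0 in model II because
# only the sum g_y + beta*E is identifiable there; E is fixed at 1 during
# fitting (the dose multiplier is absorbed into mu/beta/k_f).
free_params_for <- function(model_id) {
  switch(model_id,
    I_mutation = c("g_x", "g_y", "mu"),
    II_proliferation = c("g_x", "beta"),
    III_plasticity = c("k_f", "k_r"))
}

fit_rss <- function(model_id, free, theta, data) {
  p <- as.list(treg_params())
  p[free] <- as.list(pmax(theta, 0))
  traj <- simulate_treg(model_id, do.call(treg_params, p),
                        x0 = data$x_obs[1L], y0 = data$y_obs[1L],
                        times = data$times)
  rss <- sum((log1p(data$x_obs) - log1p(traj$x))^2 +
             (log1p(data$y_obs) - log1p(traj$y))^2)
  # runaway-growth parameter regions overflow to Inf; keep the objective
  # finite so bounded L-BFGS-B can retreat from them
  if (!is.finite(rss)) 1e12 else rss
}

#' Fit one conversion model to trajectory data
#'
#' Minimises the residual sum of squares between `log1p`-transformed
#' observed and simulated abundances over the model's free rates, with
#' non-negativity bounds and multi-start `L-BFGS-B` local optimisation
#' (starts drawn log-uniformly on \[1e-4, 1\] per hour, seeded for
#' reproducibility). Initial abundances are pinned to the first observation.
#' The log1p scale keeps counts spanning orders of magnitude comparable and
#' tolerates zeros.
#'
#' @param model_id model identifier, see [treg_model()].
#' @param data a [trajectory_dataset()] with at least 4 time points.
#' @param n_starts number of optimiser starts (>= 1; default 8).
#' @param seed integer seed for start sampling.
#' @return an object of class `treg_fit`: `model_id`, `params` (full
#'   [treg_params()] with fitted values substituted), `free` (named fitted
#'   vector), `loss` (RSS), `n_obs`, `k` (number of free parameters) and
#'   `aic = 2k + n_obs * log(loss / n_obs)` (loss floored at 1e-12 so the
#'   score stays finite on noise-free data).
#' @export
fit_treg_model <- function(model_id, data, n_starts = 8L, seed = 1L) {
  model_id <- treg_model(model_id)
  stopifnot(inherits(data, "trajectory_dataset"))
  if (length(data$times) < 4L)
    stop("need at least 4 time points to fit", call. = FALSE)
  free <- free_params_for(model_id)
  k <- length(free)
  obj <- function(theta) fit_rss(model_id, free, theta, data)
  starts <- local({
    set.seed(seed)
    m <- matrix(10^stats::runif(n_starts * k, -4, 0), n_starts, k)
    m[1L, ] <- 0.05  # one deterministic mid-range start
    m
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = rep(0, k), upper = rep(10, k),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all ", n_starts, " optimiser starts failed for model ", model_id,
         call. = FALSE)
  theta <- stats::setNames(pmax(best$par, 0), free)
  p <- as.list(treg_params())
  p[free] <- as.list(theta)
  n_obs <- 2L * length(data$times)
  loss <- best$value
  structure(list(model_id = model_id,
                 params = do.call(treg_params, p),
                 free = theta, loss = loss, n_obs = n_obs, k = k,
                 aic = 2 * k + n_obs * log(max(loss, 1e-12) / n_obs),
                 convergence = best$convergence),
            class = "treg_fit")
}

#' @export
print.treg_fit <- function(x, ...) {
  cat("<treg_fit>", x$model_id, "| loss", format(x$loss, digits = 4),
      "| AIC", format(x$aic, digits = 5), "\n")
  print(round(x$free, 5))
  invisible(x)
}

#' Fit and rank all three conversion models
#'
#' Fits models I, II and III to the same data and ranks them by AIC
#' (ascending). Ties are broken by fewer free parameters, then by the fixed
#' model order I < II < III.
#'
#' @inheritParams fit_treg_model
#' @return a list of `treg_fit` objects sorted best-first, with class
#'   `treg_model_ranking`.
#' @export
#' @examples
#' d <- generate_trajectories("III", treg_params(k_f = 0.2, k_r = 0.05),
#'                            x0 = 1000, y0 = 10,
#'                            times = seq(0, 72, length.out = 20),
#'                            noise_sd = 0.05, seed = 11)
#' select_treg_model(d)[[1]]$model_id
select_treg_model <- function(data, n_starts = 8L, seed = 1L) {
  ids <- c("I_mutation", "II_proliferation", "III_plasticity")
  fits <- lapply(ids, function(m)
    tryCatch(fit_treg_model(m, data, n_starts = n_starts, seed = seed),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (sum(ok) < 2L)
    stop("model selection needs at least 2 successful fits; errors: ",
         paste(vapply(fits[!ok], conditionMessage, character(1)),
               collapse = "; "), call. = FALSE)
  fits <- fits[ok]
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  ord <- order(aic, kk, match(vapply(fits, `[[`, character(1), "model_id"),
                              ids))
  structure(fits[ord], class = "treg_model_ranking")
}

#' @export
print.treg_model_ranking <- function(x, ...) {
  cat("<treg_model_ranking>\n")
  for (i in seq_along(x))
    cat(sprintf("  %d. %-17s AIC %10.3f  loss %.4g\n", i, x[[i]]$model_id,
                x[[i]]$aic, x[[i]]$loss))
  invisible(x)
}
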