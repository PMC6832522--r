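# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: scalar closed forms instead of the matrix
# exponential, a double loop instead of the vectorised box counter,
# stats::wilcox.test instead of the in-package rank test.

# Hand-derived solutions of the three linear models (a != b assumed where
# it matters; callers pick parameters accordingly).
oracle_model_I <- function(p, x0, y0, t) {
  a <- p$g_x - p$mu * p$E
  b <- p$g_y
  x <- x0 * exp(a * t)
  y <- if (abs(a - b) > 1e-12) {
    y0 * exp(b * t) + p$mu * p$E * x0 * (exp(a * t) - exp(b * t)) / (a - b)
  } else {
    y0 * exp(b * t) + p$mu * p$E * x0 * t * exp(b * t)
  }
  cbind(x = x, y = y)
}

oracle_model_II <- function(p, x0, y0, t) {
  cbind(x = x0 * exp(p$g_x * t),
        y = y0 * exp((p$g_y + p$beta * p$E) * t))
}

oracle_model_III <- function(p, x0, y0, t) {
  kf <- p$k_f * p$E
  kr <- p$k_r
  tot <- x0 + y0
  yss <- kf / (kf + kr)
  y <- yss * tot + (y0 - yss * tot) * exp(-(kf + kr) * t)
  cbind(x = tot - y, y = y)
}

oracle_simulate <- function(model_id, p, x0, y0, t) {
  switch(model_id,
         I_mutation = oracle_model_I(p, x0, y0, t),
         II_proliferation = oracle_model_II(p, x0, y0, t),
         III_plasticity = oracle_model_III(p, x0, y0, t))
}

# Matrix-exponential route (Matrix::expm), one time point at a time.
oracle_expm <- function(model_id, p, x0, y0, t) {
  A <- tregswitch:::model_matrix(model_id, p)
  t(vapply(t, function(tt)
    as.vector(Matrix::expm(Matrix::Matrix(A * tt)) %*% c(x0, y0)),
    numeric(2)))
}

# Brute-force box counting / mass moments with an explicit double loop.
naive_box_stats <- function(px, eps) {
  masses <- c()
  for (i in seq(1L, nrow(px), by = eps))
    for (j in seq(1L, ncol(px), by = eps)) {
      blk <- px[i:min(i + eps - 1L, nrow(px)),
                j:min(j + eps - 1L, ncol(px)), drop = FALSE]
      masses <- c(masses, sum(blk))
    }
  list(occupied = sum(masses > 0),
       mass_mean = mean(masses),
       mass_var = mean(masses^2) - mean(masses)^2)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

random_params <- function(model_id) {
  r <- function() stats::runif(1, 0.01, 0.3)
  switch(model_id,
         I_mutation = treg_params(g_x = r(), g_y = r(), mu = r()),
         II_proliferation = treg_params(g_x = r(), g_y = r(), beta = r()),
         III_plasticity = treg_params(k_f = r(), k_r = r()))
}
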