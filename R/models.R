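#' Competing models of Treg enrichment
#'
#' Three linear two-compartment models describe how a culture of non-Treg
#' CD4+ cells (\eqn{X}) and FOXP3+ Treg-like cells (\eqn{Y}) can become
#' Treg-enriched after exposure to tumour-derived exosomes (TDEs):
#'
#' \describe{
#'   \item{`I_mutation`}{heritable acquisition: exposed non-Tregs acquire the
#'     Treg phenotype irreversibly at rate \eqn{\mu E} while both
#'     compartments grow,
#'     \eqn{dX/dt = g_x X - \mu E X}, \eqn{dY/dt = g_y Y + \mu E X}.}
#'   \item{`II_proliferation`}{expansion of pre-existing Tregs: the dose only
#'     boosts Treg proliferation,
#'     \eqn{dX/dt = g_x X}, \eqn{dY/dt = (g_y + \beta E) Y}.}
#'   \item{`III_plasticity`}{reversible phenotypic switching with conserved
#'     total population,
#'     \eqn{dX/dt = -k_f E X + k_r Y}, \eqn{dY/dt = k_f E X - k_r Y}.}
#' }
#'
#' Only model III saturates: its Treg fraction relaxes to the fixed point
#' \eqn{k_f E / (k_f E + k_r)} while \eqn{X + Y} stays constant, whereas
#' models I and II keep growing whenever the net Treg growth rate is
#' positive. That dichotomy is what lets saturating conversion data reject
#' the proliferation explanation.
#'
#' @param model_id one of `"I_mutation"`, `"II_proliferation"`,
#'   `"III_plasticity"` (unambiguous prefixes such as `"III"` are accepted).
#' @return `treg_model()` returns the validated canonical model identifier.
#' @seealso [treg_params()], [simulate_treg()], [steady_state_fraction()]
#' @export
#' @examples
#' treg_model("III")
treg_model <- function(model_id) {
  ids <- c("I_mutation", "II_proliferation", "III_plasticity")
  if (!is.character(model_id) || length(model_id) != 1L || is.na(model_id))
    stop("model_id must be a single string", call. = FALSE)
  # roman-numeral shorthand first ("I" would otherwise prefix-match all three)
  short <- c(I = "I_mutation", II = "II_proliferation", III = "III_plasticity")
  if (model_id %in% names(short)) return(unname(short[[model_id]]))
  hit <- ids[startsWith(ids, model_id)]
  if (length(hit) != 1L)
    stop("unknown model_id: ", model_id, " (expected one of ",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  hit
}

#' Rate constants for the Treg conversion models
#'
#' All rates are per-capita and in 1/hour. Parameters not used by a given
#' model are ignored there but must still be finite and non-negative.
#'
#' @param g_x,g_y per-capita growth rates of non-Tregs (X) and Tregs (Y).
#' @param mu phenotype-acquisition rate (model I).
#' @param beta exosome-driven proliferation increment for Tregs (model II).
#' @param k_f,k_r forward (X to Y) and reverse (Y to X) switching rates
#'   (model III).
#' @param E exosome dose, a unitless multiplier applied to `mu`, `beta` and
#'   `k_f` only; defaults to 1.
#' @return an object of class `treg_params` (a named list of rates).
#' @export
#' @examples
#' treg_params(k_f = 0.2, k_r = 0.05)
treg_params <- function(g_x = 0, g_y = 0, mu = 0, beta = 0,
                        k_f = 0, k_r = 0, E = 1) {
  p <- list(g_x = g_x, g_y = g_y, mu = mu, beta = beta,
            k_f = k_f, k_r = k_r, E = E)
  bad <- vapply(p, function(v)
    !is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("all rates must be single finite non-negative numbers; offending: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "treg_params")
}

# System matrix A such that d/dt (x, y) = A (x, y).
model_matrix <- function(model_id, params) {
  model_id <- treg_model(model_id)
  p <- params
  switch(model_id,
    I_mutation = matrix(c(p$g_x - p$mu * p$E, p$mu * p$E,
                          0, p$g_y), 2L, 2L),
    II_proliferation = matrix(c(p$g_x, 0,
                                0, p$g_y + p$beta * p$E), 2L, 2L),
    III_plasticity = matrix(c(-p$k_f * p$E, p$k_f * p$E,
                              p$k_r, -p$k_r), 2L, 2L))
}

# exp(A t) %*% v for a 2x2 matrix with real eigenvalues, vectorised over t.
# Uses A = l2*I + N with N^2 = (l1-l2) N (Cayley-Hamilton), so
# exp(A t) v = exp(l2 t) * (v + t*phi((l1-l2) t) * N v),  phi(z)=expm1(z)/z.
# Stable for (near-)degenerate eigenvalues; our Metzler matrices (non-negative
# off-diagonals) always have a real spectrum.
expm2_apply <- function(A, v, times) {
  if (A[1L, 2L] == 0 || A[2L, 1L] == 0) {
    # triangular (models I and II): eigenvalues are the diagonal entries,
    # exactly -- avoids 1-ulp eigenvalue error being amplified by e^(l1 t)
    l1 <- max(A[1L, 1L], A[2L, 2L])
    l2 <- min(A[1L, 1L], A[2L, 2L])
  } else {
    h <- (A[1L, 1L] - A[2L, 2L]) / 2
    disc <- sqrt(h * h + A[1L, 2L] * A[2L, 1L])  # real: Metzler matrix
    mid <- (A[1L, 1L] + A[2L, 2L]) / 2
    l1 <- mid + disc
    l2 <- mid - disc
  }
  N <- A - diag(l2, 2L)
  w <- as.vector(N %*% v)
  z <- (l1 - l2) * times
  c0 <- exp(l2 * times)
  # c1 = (e^{l1 t} - e^{l2 t}) / (l1 - l2): expm1 form for small z avoids
  # cancellation, direct form for large z avoids exp(l2 t) * Inf = NaN
  c1 <- ifelse(abs(z) < 1,
               c0 * times * ifelse(z == 0, 1, expm1(z) / z),
               (exp(l1 * times) - c0) / (l1 - l2))
  cbind(x = c0 * v[1L] + c1 * w[1L],
        y = c0 * v[2L] + c1 * w[2L])
}

#' Simulate a Treg conversion model
#'
#' Integrates the chosen linear model exactly via its 2x2 matrix exponential
#' (closed form; no numerical ODE stepping), evaluated on an arbitrary time
#' grid. Round-off-level negative values are clipped to zero.
#'
#' @param model_id model identifier, see [treg_model()].
#' @param params a [treg_params()] object.
#' @param x0,y0 initial non-Treg and Treg abundances (cells, >= 0).
#' @param times strictly increasing time grid in hours, first point >= 0.
#' @return an object of class `treg_trajectory`: a list with `times`, `x`,
#'   `y` and `treg_fraction` (`y/(x+y)`, `NA` where the total is zero).
#' @export
#' @examples
#' tr <- simulate_treg("III", treg_params(k_f = 0.2, k_r = 0.05),
#'                     x0 = 1000, y0 = 0, times = seq(0, 72, by = 2))
#' tail(tr$treg_fraction, 1)  # approaches 0.2/(0.2+0.05) = 0.8
simulate_treg <- function(model_id, params, x0, y0, times) {
  model_id <- treg_model(model_id)
  stopifnot(inherits(params, "treg_params"))
  if (!is.numeric(x0) || !is.numeric(y0) || x0 < 0 || y0 < 0 ||
      !is.finite(x0) || !is.finite(y0))
    stop("x0 and y0 must be finite and non-negative", call. = FALSE)
  check_time_grid(times)
  A <- model_matrix(model_id, params)
  # integrate from t = times[1] (grid need not start at 0)
  sol <- expm2_apply(A, c(x0, y0), times - times[1L])
  x <- pmax(sol[, "x"], 0)
  y <- pmax(sol[, "y"], 0)
  tot <- x + y
  structure(list(model_id = model_id, params = params,
                 times = times, x = x, y = y,
                 treg_fraction = ifelse(tot > 0, y / tot, NA_real_)),
            class = "treg_trajectory")
}

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times) ||
      times[1L] < 0 || any(diff(times) <= 0))
    stop("times must be a strictly increasing numeric grid starting >= 0",
         call. = FALSE)
  invisible(times)
}

#' @export
print.treg_trajectory <- function(x, ...) {
  cat("<treg_trajectory> model", x$model_id, "-", length(x$times),
      "time points over", format(diff(range(x$times))), "h\n")
  cat("  terminal X:", format(tail_1(x$x)),
      " Y:", format(tail_1(x$y)),
      " Treg fraction:", format(tail_1(x$treg_fraction)), "\n")
  invisible(x)
}

tail_1 <- function(v) v[length(v)]

#' Analytic steady-state Treg fraction of the plasticity model
#'
#' For model III the Treg fraction relaxes to
#' \eqn{k_f E / (k_f E + k_r)} regardless of initial conditions.
#'
#' @param params a [treg_params()] object with model III rates.
#' @return the fixed-point Treg fraction in \[0, 1\].
#' @export
#' @examples
#' steady_state_fraction(treg_params(k_f = 3, k_r = 1))  # 0.75
steady_state_fraction <- function(params) {
  stopifnot(inherits(params, "treg_params"))
  kf <- params$k_f * params$E
  kr <- params$k_r
  if (kf + kr <= 0)
    stop("steady state undefined: k_f*E + k_r must be positive",
         call. = FALSE)
  kf / (kf + kr)
}

#' Classify the long-run regime of a trajectory
#'
#' Looks at the relative change of the total population X+Y over the
#' trailing fraction `window` of the time grid: within `tol` of zero is
#' `"saturating"`, above is `"growing"`, below is `"declining"`. The
#' saturating/growing dichotomy separates the plasticity model (conserved
#' total) from the mutation and proliferation models (unbounded growth for
#' positive net rates).
#'
#' @param traj a `treg_trajectory` (from [simulate_treg()]) or any list with
#'   `times`, `x`, `y`.
#' @param window trailing fraction of the time span inspected (default 0.2).
#' @param tol relative-change threshold (default 0.01, i.e. 1%).
#' @return one of `"growing"`, `"saturating"`, `"declining"`.
#' @export
classify_regime <- function(traj, window = 0.2, tol = 0.01) {
  if (length(traj$times) < 10L)
    stop("trajectory must have at least 10 time points", call. = FALSE)
  if (!is.numeric(window) || window <= 0 || window >= 1)
    stop("window must lie strictly between 0 and 1", call. = FALSE)
  total <- traj$x + traj$y
  t0 <- tail_1(traj$times) - window * diff(range(traj$times))
  i0 <- which(traj$times >= t0)[1L]
  if (total[i0] <= 0)
    stop("total population is zero at the window start", call. = FALSE)
  rel <- (tail_1(total) - total[i0]) / total[i0]
  if (abs(rel) < tol) "saturating" else if (rel > 0) "growing" else "declining"
}
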