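#' Default fluorescence channel model for synthetic flow events
#'
#' Each population is log-normal per channel, the usual first-order picture
#' of cytometry fluorescence. All events are CD4-bright (the assay starts
#' from purified CD4+ cells); the FOXP3 channel is a two-component mixture
#' with well-separated low and high modes.
#'
#' @return a named list of `c(meanlog, sdlog)` vectors for the `CD4`
#'   channel and the `FOXP3_low` / `FOXP3_high` mixture components.
#' @export
default_flow_channels <- function() {
  # FOXP3 modes sit > 3 sdlog on either side of the default gate, so the
  # gated fraction tracks the mixture weight to ~5e-4 — the generator's
  # contract that gated fraction ~ converted_fraction.
  list(CD4        = c(meanlog = log(800),  sdlog = 0.35),
       FOXP3_low  = c(meanlog = log(100),  sdlog = 0.35),
       FOXP3_high = c(meanlog = log(1000), sdlog = 0.35))
}

#' Default CD4+FOXP3+ rectangular gate
#'
#' Thresholds sit between the modes of [default_flow_channels()]: the FOXP3
#' cut at the geometric midpoint of the low and high components, the CD4 cut
#' well below the CD4+ mode. An event is gate-positive when every channel
#' strictly exceeds its threshold.
#'
#' @return a [gate_definition()].
#' @export
default_treg_gate <- function() {
  ch <- default_flow_channels()
  gate_definition(c(
    CD4 = 150,
    FOXP3 = exp((ch$FOXP3_low[["meanlog"]] + ch$FOXP3_high[["meanlog"]]) / 2)))
}

#' Generate a synthetic flow-cytometry event table
#'
#' Draws `n_events` cells from a two-component mixture: a FOXP3-low
#' (unconverted) and a FOXP3-high (converted, Treg-like) population, each
#' log-normal per channel. The expected fraction of events passing
#' [default_treg_gate()] is approximately `converted_fraction` because the
#' mixture components sit almost entirely on either side of the gate.
#'
#' @param n_events number of cells (>= 1).
#' @param converted_fraction probability a cell belongs to the FOXP3-high
#'   component, in \[0, 1\].
#' @param channel_params population location/scale list as returned by
#'   [default_flow_channels()].
#' @param condition label attached to the table (e.g. `"MT-TDE"`).
#' @param seed integer RNG seed; output is bit-identical for a given seed.
#' @return a `flow_events` data frame with numeric columns `CD4` and
#'   `FOXP3`, a logical column `converted` (true mixture membership), and a
#'   `condition` attribute.
#' @export
#' @examples
#' ev <- generate_flow_events(5000, 0.3, seed = 1)
#' gate_fraction(ev, default_treg_gate())
generate_flow_events <- function(n_events, converted_fraction,
                                 channel_params = default_flow_channels(),
                                 condition = "synthetic", seed = 1L) {
  if (!is.numeric(n_events) || n_events < 1)
    stop("n_events must be >= 1", call. = FALSE)
  if (!is.numeric(converted_fraction) || is.na(converted_fraction) ||
      converted_fraction < 0 || converted_fraction > 1)
    stop("converted_fraction must lie in [0, 1]", call. = FALSE)
  sds <- vapply(channel_params, `[[`, numeric(1), "sdlog")
  if (any(sds <= 0))
    stop("channel sdlog values must be positive", call. = FALSE)
  n_events <- as.integer(n_events)
  set.seed(seed)
  converted <- stats::runif(n_events) < converted_fraction
  cd4 <- stats::rlnorm(n_events, channel_params$CD4[["meanlog"]],
                       channel_params$CD4[["sdlog"]])
  lo <- channel_params$FOXP3_low
  hi <- channel_params$FOXP3_high
  foxp3 <- stats::rlnorm(n_events,
                         ifelse(converted, hi[["meanlog"]], lo[["meanlog"]]),
                         ifelse(converted, hi[["sdlog"]], lo[["sdlog"]]))
  out <- data.frame(CD4 = cd4, FOXP3 = foxp3, converted = converted)
  attr(out, "condition") <- condition
  class(out) <- c("flow_events", "data.frame")
  out
}

#' Generate noisy trajectory observations from a conversion model
#'
#' Simulates the noise-free solution with [simulate_treg()] and applies
#' multiplicative log-normal observation noise (counts span orders of
#' magnitude, so noise is naturally proportional): `x_obs = x *
#' exp(N(0, noise_sd))`. Exact zeros stay zero and values are clipped at 0.
#' With `noise_sd = 0` the output equals the exact solution.
#'
#' @inheritParams simulate_treg
#' @param noise_sd log-scale observation-noise SD (>= 0).
#' @param seed integer RNG seed.
#' @return a [trajectory_dataset()].
#' @export
generate_trajectories <- function(model_id, params, x0, y0, times,
                                  noise_sd = 0.05, seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  traj <- simulate_treg(model_id, params, x0, y0, times)
  n <- length(times)
  if (noise_sd > 0) {
    set.seed(seed)
    x_obs <- pmax(traj$x * exp(stats::rnorm(n, 0, noise_sd)), 0)
    y_obs <- pmax(traj$y * exp(stats::rnorm(n, 0, noise_sd)), 0)
  } else {
    x_obs <- traj$x
    y_obs <- traj$y
  }
  trajectory_dataset(times, x_obs, y_obs, noise_sd = noise_sd)
}

#' Construct a binary image
#'
#' @param pixels logical matrix, foreground = `TRUE` (marker-positive).
#' @param provenance free-form source label (group id, slide id, pattern).
#' @return an object of class `binary_image`.
#' @export
binary_image <- function(pixels, provenance = "unknown") {
  if (is.numeric(pixels)) pixels <- pixels > 0
  if (!is.logical(pixels) || !is.matrix(pixels) ||
      nrow(pixels) < 2L || ncol(pixels) < 2L || anyNA(pixels))
    stop("pixels must be a logical matrix with at least 2 pixels per side",
         call. = FALSE)
  structure(list(pixels = pixels, provenance = provenance),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat("<binary_image>", nrow(x$pixels), "x", ncol(x$pixels), "|",
      sum(x$pixels), "foreground px |", x$provenance, "\n")
  invisible(x)
}

# 0-based (i, j) is in the Sierpinski carpet iff no base-3 digit pair is
# (1, 1); origin-anchored, exact analytic FD fixture (log 8 / log 3).
carpet_mask <- function(side) {
  i <- matrix(rep(0:(side - 1L), times = side), side, side)
  j <- matrix(rep(0:(side - 1L), each = side), side, side)
  fg <- matrix(TRUE, side, side)
  while (any(i > 0 | j > 0)) {
    fg <- fg & !((i %% 3L == 1L) & (j %% 3L == 1L))
    i <- i %/% 3L
    j <- j %/% 3L
  }
  fg
}

#' Generate a synthetic spatial marker image
#'
#' Produces binary images with the spatial structure relevant to
#' fractal-dimension / lacunarity analysis of immune-cell distributions:
#' dense clustered point patterns (Treg-enriched, mutant-like tissue),
#' sparse uniform patterns (wild-type-like tissue), and exact analytic
#' fixtures (solid, empty, Sierpinski carpet).
#'
#' Point patterns place exactly `n_points` distinct foreground pixels
#' (collision-free). The Sierpinski carpet is anchored at the image origin
#' on the largest power-of-3 side that fits (at least 27, i.e. 3
#' subdivision levels); remaining pixels are background padding and the
#' effective side is recorded in the provenance string.
#'
#' @param shape integer length-2 vector, image height and width in pixels.
#' @param pattern one of `"uniform_random"`, `"clustered"`,
#'   `"sierpinski_carpet"`, `"solid"`, `"empty"`.
#' @param n_points number of foreground pixels for point patterns.
#' @param cluster_count,cluster_sd number of Gaussian clusters and their SD
#'   in pixels (pattern `"clustered"`).
#' @param seed integer RNG seed (point patterns are deterministic given it).
#' @param provenance optional source label.
#' @return a [binary_image()].
#' @export
#' @examples
#' img <- generate_spatial_image(c(81, 81), "sierpinski_carpet")
#' sum(img$pixels)  # 8^4 = 4096
generate_spatial_image <- function(shape, pattern = c("uniform_random",
                                                      "clustered",
                                                      "sierpinski_carpet",
                                                      "solid", "empty"),
                                   n_points = 500L, cluster_count = 10L,
                                   cluster_sd = 5, seed = 1L,
                                   provenance = NULL) {
  pattern <- match.arg(pattern)
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop("shape must be at least 2x2", call. = FALSE)
  nr <- shape[1L]; nc <- shape[2L]
  if (is.null(provenance)) provenance <- pattern
  px <- matrix(FALSE, nr, nc)

  if (pattern == "solid") {
    px[] <- TRUE
  } else if (pattern == "empty") {
    # valid as an image; metric functions reject it downstream
  } else if (pattern == "sierpinski_carpet") {
    if (min(nr, nc) < 27L)
      stop("sierpinski_carpet needs shape >= 27x27 (3 subdivision levels)",
           call. = FALSE)
    levels <- floor(log(min(nr, nc)) / log(3) + 1e-9)
    side <- 3L^levels
    px[seq_len(side), seq_len(side)] <- carpet_mask(side)
    provenance <- sprintf("%s(side=%d,levels=%d)", provenance, side, levels)
  } else {
    n_points <- as.integer(n_points)
    if (n_points < 1L || n_points > nr * nc)
      stop("n_points must be in [1, pixel count]", call. = FALSE)
    set.seed(seed)
    if (pattern == "uniform_random") {
      px[sample.int(nr * nc, n_points)] <- TRUE
    } else {  # clustered
      centers <- cbind(stats::runif(cluster_count, 1, nr),
                       stats::runif(cluster_count, 1, nc))
      chosen <- integer(0)
      guard <- 0L
      while (length(chosen) < n_points && guard < 50L) {
        need <- n_points - length(chosen)
        idx <- sample.int(cluster_count, need, replace = TRUE)
        i <- pmin(pmax(round(centers[idx, 1L] +
                               stats::rnorm(need, 0, cluster_sd)), 1L), nr)
        j <- pmin(pmax(round(centers[idx, 2L] +
                               stats::rnorm(need, 0, cluster_sd)), 1L), nc)
        chosen <- unique(c(chosen, (j - 1L) * nr + i))
        guard <- guard + 1L
      }
      if (length(chosen) < n_points)
        stop("could not place ", n_points, " distinct clustered points; ",
             "increase image size or cluster_sd", call. = FALSE)
      px[chosen[seq_len(n_points)]] <- TRUE
    }
  }
  binary_image(px, provenance = provenance)
}

#' Configuration for the synthetic single-cell count generator
#'
#' @param n_genes number of genes (> 0).
#' @param n_cells_per_group named integer vector of cells per group; must
#'   cover `WT`, `MT` and `TREG`.
#' @param isg_gene_ids character vector of genes designated
#'   interferon-stimulated (must be a subset of the gene names
#'   `"G1"..."Gn"`); default `G1..G10`.
#' @param mt_responder_fraction fraction of MT-treated cells with elevated
#'   ISG expression, in \[0, 1\].
#' @param baseline_mean negative-binomial mean of an unperturbed gene
#'   (counts per cell; > 0).
#' @param effect_multiplier fold-increase of ISG means in TREG cells and in
#'   MT responders (>= 0; 1 switches the effect off).
#' @param dropout_rate probability a true count is zeroed by technical
#'   dropout, in \[0, 1).
#' @param dispersion negative-binomial `size` parameter (smaller = more
#'   overdispersed).
#' @return an object of class `scrna_config`.
#' @export
scrna_config <- function(n_genes = 200L,
                         n_cells_per_group = c(WT = 1000L, MT = 1000L,
                                               TREG = 1000L),
                         isg_gene_ids = paste0("G", 1:10),
                         mt_responder_fraction = 0.15,
                         baseline_mean = 2,
                         effect_multiplier = 8,
                         dropout_rate = 0.2,
                         dispersion = 4) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  need <- c("WT", "MT", "TREG")
  if (!all(need %in% names(n_cells_per_group)) ||
      any(n_cells_per_group[need] < 1L))
    stop("n_cells_per_group must name positive WT, MT and TREG sizes",
         call. = FALSE)
  genes <- paste0("G", seq_len(n_genes))
  if (!all(isg_gene_ids %in% genes))
    stop("isg_gene_ids must be a subset of the gene names G1..G", n_genes,
         call. = FALSE)
  if (mt_responder_fraction < 0 || mt_responder_fraction > 1)
    stop("mt_responder_fraction must lie in [0, 1]", call. = FALSE)
  if (baseline_mean <= 0 || effect_multiplier < 0 || dispersion <= 0)
    stop("baseline_mean and dispersion must be > 0, effect_multiplier >= 0",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(n_genes = n_genes,
                 n_cells_per_group = as.integer(n_cells_per_group[need]),
                 genes = genes, isg_gene_ids = isg_gene_ids,
                 mt_responder_fraction = mt_responder_fraction,
                 baseline_mean = baseline_mean,
                 effect_multiplier = effect_multiplier,
                 dropout_rate = dropout_rate, dispersion = dispersion),
            class = "scrna_config")
}

#' Generate a synthetic three-group single-cell count matrix
#'
#' Emulates the group structure of an exosome-conversion single-cell
#' experiment: naive CD4+ cells treated with wild-type TDEs (`WT`), cells
#' treated with mutant-KRAS TDEs (`MT`), and bona fide Tregs (`TREG`).
#' Counts are negative binomial with fixed dispersion plus independent
#' Bernoulli dropout. Interferon-stimulated genes (ISGs) have mean
#' `effect_multiplier * baseline_mean` in all TREG cells and in a random
#' `mt_responder_fraction` subset of MT cells, and `baseline_mean`
#' everywhere else; the responder count is fixed at
#' `round(fraction * n_MT)`.
#'
#' @param config an [scrna_config()].
#' @param seed integer RNG seed.
#' @return an object of class `count_matrix`: integer `counts` (genes x
#'   cells), `genes`, `cells`, per-cell `group` factor, and the logical
#'   `mt_responder` flag per cell.
#' @export
generate_scrna_counts <- function(config = scrna_config(), seed = 1L) {
  stopifnot(inherits(config, "scrna_config"))
  set.seed(seed)
  n <- config$n_cells_per_group
  groups <- factor(rep(c("WT", "MT", "TREG"), times = n),
                   levels = c("WT", "MT", "TREG"))
  n_cells <- sum(n)
  cells <- paste0("C", seq_len(n_cells))
  responder <- rep(FALSE, n_cells)
  mt_idx <- which(groups == "MT")
  n_resp <- round(config$mt_responder_fraction * length(mt_idx))
  if (n_resp > 0)
    responder[sample(mt_idx, n_resp)] <- TRUE
  elevated <- responder | groups == "TREG"

  mu <- matrix(config$baseline_mean, config$n_genes, n_cells,
               dimnames = list(config$genes, cells))
  isg <- match(config$isg_gene_ids, config$genes)
  if (length(isg))
    mu[isg, elevated] <- config$baseline_mean * config$effect_multiplier
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = config$dispersion),
                   config$n_genes, n_cells,
                   dimnames = dimnames(mu))
  if (config$dropout_rate > 0) {
    keep <- stats::runif(length(counts)) >= config$dropout_rate
    counts <- counts * keep
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, genes = config$genes, cells = cells,
                 group = groups, mt_responder = responder,
                 config = config),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "genes x", ncol(x$counts),
      "cells |", paste(levels(x$group), table(x$group), collapse = ", "),
      "\n")
  invisible(x)
}
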