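#' Rectangular flow-cytometry gate
#'
#' A gate is a set of per-channel intensity thresholds; an event is
#' gate-positive when it strictly exceeds every threshold (all-of rule).
#'
#' @param thresholds named numeric vector of channel thresholds
#'   (intensity units); at least one channel, all finite... `-Inf`/`Inf`
#'   are allowed as always-pass / never-pass cuts.
#' @return an object of class `gate_definition`.
#' @export
#' @examples
#' gate_definition(c(CD4 = 150, FOXP3 = 316))
gate_definition <- function(thresholds) {
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      is.null(names(thresholds)) || any(!nzchar(names(thresholds))) ||
      anyNA(thresholds))
    stop("thresholds must be a named, non-NA numeric vector", call. = FALSE)
  structure(list(thresholds = thresholds), class = "gate_definition")
}

#' Fraction of events passing a gate
#'
#' @param events a `flow_events` data frame (see [generate_flow_events()])
#'   or any data frame with the gated channels as numeric columns.
#' @param gate a [gate_definition()]; its channels must all be present in
#'   `events`.
#' @return the proportion of events strictly above every threshold.
#' @export
gate_fraction <- function(events, gate) {
  stopifnot(inherits(gate, "gate_definition"))
  ch <- names(gate$thresholds)
  missing <- setdiff(ch, names(events))
  if (length(missing))
    stop("gate channels absent from event table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(events) < 1L) stop("empty event table", call. = FALSE)
  pass <- rep(TRUE, nrow(events))
  for (c_ in ch) pass <- pass & (events[[c_]] > gate$thresholds[[c_]])
  mean(pass)
}

#' Fold conversion between treated and control event tables
#'
#' Ratio of gate-positive fractions, treated over control — the flow
#' readout quantifying how strongly a treatment (e.g. mutant-KRAS
#' tumour-derived exosomes) converts CD4+ cells into CD4+FOXP3+ Treg-like
#' cells. Computed on fractions, not counts, so unequal acquisition depths
#' cancel.
#'
#' @param treated,control `flow_events` tables (non-empty).
#' @param gate a [gate_definition()].
#' @return a list of class `conversion_result`: `fraction_treated`,
#'   `fraction_control`, `fold`, `n_treated`, `n_control`.
#' @export
fold_conversion <- function(treated, control, gate = default_treg_gate()) {
  ft <- gate_fraction(treated, gate)
  fc <- gate_fraction(control, gate)
  if (fc == 0)
    stop("fold conversion undefined: control has no gate-positive events",
         call. = FALSE)
  structure(list(fraction_treated = ft, fraction_control = fc,
                 fold = ft / fc,
                 n_treated = nrow(treated), n_control = nrow(control)),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf(
    "<conversion_result> %.4f (n=%d) vs %.4f (n=%d): fold = %.3f\n",
    x$fraction_treated, x$n_treated, x$fraction_control, x$n_control,
    x$fold))
  invisible(x)
}

#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' The U statistic is computed from midrank-based rank sums. The p-value is
#' exact — from the full null distribution of U, enumerated over all
#' placements of the x-ranks — when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used. Only the two-sided alternative is
#' offered, matching the convention of reporting group differences in
#' cohort comparisons.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max combined-size cutover for the exact null distribution
#'   (documented constant, default 12).
#' @return a list with `statistic` (U of `x`), `p.value`, `exact` flag and
#'   `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (nx + ny) <= exact_max
  if (exact) {
    dist <- u_null_distribution(nx, ny)
    mn <- nx * ny
    lo <- min(u, mn - u)
    p <- min(1, 2 * sum(dist$prob[dist$u <= lo]))
    method <- "exact enumeration"
  } else {
    mn <- nx * ny
    nt <- nx + ny
    tie_sizes <- table(c(x, y))
    sigma2 <- mn / 12 * ((nt + 1) -
                           sum(tie_sizes^3 - tie_sizes) / (nt * (nt - 1)))
    z <- u - mn / 2
    z <- z - sign(z) * 0.5  # continuity correction
    p <- if (sigma2 <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z) /
                                                           sqrt(sigma2)))
    method <- "normal approximation with tie/continuity correction"
  }
  list(statistic = u, p.value = p, exact = exact, method = method,
       n_x = nx, n_y = ny)
}

# Exact null distribution of U for sample sizes (m, n) without ties,
# enumerated over all C(m+n, m) placements of the x-ranks.
u_null_distribution <- function(m, n) {
  combos <- utils::combn(m + n, m)
  u <- colSums(combos) - m * (m + 1) / 2
  tab <- table(u)
  list(u = as.numeric(names(tab)),
       prob = as.numeric(tab) / ncol(combos))
}

#' Per-gene upregulated-cell-fraction statistic
#'
#' For one gene, the expression threshold is the mean count of reference
#' cells (e.g. bona fide Tregs) with detectable expression — reference
#' cells with zero counts are excluded. The statistic is the percentage of
#' query cells (e.g. MT-TDE-treated naive cells) whose count is strictly
#' above that threshold. All query cells enter the denominator, including
#' zeros. If no reference cell expresses the gene the result is flagged
#' non-evaluable rather than raising an error.
#'
#' @param counts a `count_matrix` (see [generate_scrna_counts()]) or a list
#'   with integer `counts` (genes x cells) and a per-cell `group` vector.
#' @param gene gene identifier (row name).
#' @param query_group,ref_group group labels.
#' @return a list of class `upregulation_result`: `gene`, `threshold`,
#'   `fraction_above` (percent, \[0, 100\]), `n_ref_used`,
#'   `n_ref_excluded`, `n_query`, `evaluable`.
#' @export
#' @examples
#' cm <- list(counts = matrix(c(0, 2, 4, 1, 3, 4, 5), 1, 7,
#'                            dimnames = list("G1", NULL)),
#'            group = rep(c("TREG", "MT"), c(3, 4)))
#' isg_upregulated_fraction(cm, "G1", "MT", "TREG")  # threshold 3, 50%
isg_upregulated_fraction <- function(counts, gene, query_group = "MT",
                                     ref_group = "TREG") {
  m <- counts$counts
  grp <- counts$group
  if (!gene %in% rownames(m))
    stop("gene not found: ", gene, call. = FALSE)
  qi <- which(grp == query_group)
  ri <- which(grp == ref_group)
  if (!length(qi) || !length(ri))
    stop("empty query or reference group", call. = FALSE)
  ref <- m[gene, ri]
  qry <- m[gene, qi]
  used <- ref > 0
  if (!any(used)) {
    return(structure(list(gene = gene, threshold = NA_real_,
                          fraction_above = NA_real_,
                          n_ref_used = 0L, n_ref_excluded = length(ref),
                          n_query = length(qry), evaluable = FALSE),
                     class = "upregulation_result"))
  }
  thr <- mean(ref[used])
  structure(list(gene = gene, threshold = thr,
                 fraction_above = 100 * mean(qry > thr),
                 n_ref_used = sum(used),
                 n_ref_excluded = sum(!used),
                 n_query = length(qry), evaluable = TRUE),
            class = "upregulation_result")
}

#' @export
print.upregulation_result <- function(x, ...) {
  if (!x$evaluable) {
    cat("<upregulation_result>", x$gene, "non-evaluable",
        "(no reference cell expresses it)\n")
  } else {
    cat(sprintf(
      "<upregulation_result> %s: threshold %.3f (ref n=%d, %d excluded), %.1f%% of %d query cells above\n",
      x$gene, x$threshold, x$n_ref_used, x$n_ref_excluded,
      x$fraction_above, x$n_query))
  }
  invisible(x)
}

#' Upregulated-cell fractions for a set of genes
#'
#' @inheritParams isg_upregulated_fraction
#' @param genes character vector of gene ids.
#' @return a data frame with one row per gene (columns `gene`, `threshold`,
#'   `fraction_above`, `n_ref_used`, `n_ref_excluded`, `evaluable`).
#' @export
isg_fraction_table <- function(counts, genes, query_group = "MT",
                               ref_group = "TREG") {
  rows <- lapply(genes, function(g) {
    r <- isg_upregulated_fraction(counts, g, query_group, ref_group)
    data.frame(gene = r$gene, threshold = r$threshold,
               fraction_above = r$fraction_above,
               n_ref_used = r$n_ref_used,
               n_ref_excluded = r$n_ref_excluded,
               evaluable = r$evaluable)
  })
  do.call(rbind, rows)
}
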