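#' Read and write the package's plain-text interchange formats
#'
#' Flow event tables and trajectories round-trip through headered CSV.
#' Binary/grayscale images round-trip through plain-text PGM (P2) or PBM
#' (P1), chosen over PNG/TIFF so that fixtures stay human-readable and no
#' binary image codec is required. Count matrices round-trip through
#' MatrixMarket triplets with sidecar gene and cell-label files.
#'
#' @name tregswitch-io
NULL

#' @param events a `flow_events` table.
#' @param path output file.
#' @rdname tregswitch-io
#' @export
write_flow_csv <- function(events, path) {
  df <- as.data.frame(events)
  df$condition <- attr(events, "condition") %||% "unknown"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tregswitch-io
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path)
  cond <- unique(df$condition) %||% "unknown"
  df$condition <- NULL
  attr(df, "condition") <- cond[1L]
  class(df) <- c("flow_events", "data.frame")
  df
}

#' @param data a [trajectory_dataset()].
#' @rdname tregswitch-io
#' @export
write_trajectory_csv <- function(data, path) {
  utils::write.csv(data.frame(time = data$times, x_obs = data$x_obs,
                              y_obs = data$y_obs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname tregswitch-io
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "x_obs", "y_obs")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns time, x_obs, y_obs",
         call. = FALSE)
  trajectory_dataset(df$time, df$x_obs, df$y_obs)
}

#' @param img a [binary_image()] (written as P1, foreground = 1) or a
#'   numeric matrix (written as P2 grayscale).
#' @rdname tregswitch-io
#' @export
write_pnm <- function(img, path) {
  if (inherits(img, "binary_image")) {
    px <- img$pixels
    lines <- c("P1", paste(ncol(px), nrow(px)),
               apply(px * 1L, 1L, paste, collapse = " "))
  } else {
    stopifnot(is.matrix(img), is.numeric(img))
    px <- round(img)
    lines <- c("P2", paste(ncol(px), nrow(px)), max(px, 1),
               apply(px, 1L, paste, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname tregswitch-io
#' @export
read_pnm <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(trimws(raw), "#") & nzchar(trimws(raw))]
  magic <- trimws(raw[1L])
  if (!magic %in% c("P1", "P2"))
    stop("only plain-text P1/P2 PNM images are supported", call. = FALSE)
  tokens <- as.numeric(unlist(strsplit(paste(raw[-1L], collapse = " "),
                                       "[[:space:]]+")))
  tokens <- tokens[!is.na(tokens)]
  w <- tokens[1L]
  h <- tokens[2L]
  px_at <- if (magic == "P1") 3L else 4L  # P2 carries a maxval token
  vals <- tokens[px_at:(px_at + w * h - 1L)]
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (magic == "P1") binary_image(m > 0, provenance = basename(path)) else m
}

#' @param cm a `count_matrix` (see [generate_scrna_counts()]).
#' @param dir output directory; writes `counts.mtx`, `genes.txt`,
#'   `cells.txt`, `groups.txt`.
#' @rdname tregswitch-io
#' @export
write_counts_mtx <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(cm$genes, file.path(dir, "genes.txt"))
  writeLines(cm$cells, file.path(dir, "cells.txt"))
  writeLines(as.character(cm$group), file.path(dir, "groups.txt"))
  invisible(dir)
}

#' @rdname tregswitch-io
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.txt"))
  cells <- readLines(file.path(dir, "cells.txt"))
  groups <- readLines(file.path(dir, "groups.txt"))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, cells)
  structure(list(counts = m, genes = genes, cells = cells,
                 group = factor(groups)),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
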