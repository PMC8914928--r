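#' First-order contiguity spatial weights for a hexagon layer
#'
#' Two non-empty cells are neighbours iff their hexagons share an edge. For
#' a regular hexagonal tessellation edge-sharing and vertex-sharing
#' coincide, so rook and queen contiguity are the same relation. Weights are
#' binary (`w_ij = 1` for neighbours) or row-standardised (each non-isolated
#' row sums to 1), the convention used when comparing areal units.
#'
#' @param layer an aggregated `hex_layer` ([hex_aggregate()]).
#' @param style `"row"` (row-standardised, default) or `"binary"`.
#' @return An object of class `spatial_weights`: `n`, `ids` (cell ids),
#'   `neighbors` (list of integer indices into `ids`), `weights` (parallel
#'   list), `style`, and `isolated` (logical per cell).
#' @examples
#' pd <- simulate_field(field_spec(n_points = 80, seed = 1))
#' layer <- hex_aggregate(pd, make_hex_grid(bbox_of(pd), side = 60))
#' contiguity_weights(layer)
#' @export
contiguity_weights <- function(layer, style = c("row", "binary")) {
  style <- match.arg(style)
  cells <- hex_cells(layer)
  n <- nrow(cells)
  if (n < 2)
    stop("need at least 2 non-empty cells to build weights", call. = FALSE)
  key <- paste(cells$q, cells$r)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    j <- match(paste(cells$q[i] + HEX_NEIGHBOR_OFFSETS[, "q"],
                     cells$r[i] + HEX_NEIGHBOR_OFFSETS[, "r"]), key)
    nb[[i]] <- sort(j[!is.na(j)])
  }
  isolated <- lengths(nb) == 0L
  if (all(isolated))
    stop("no neighbors: every cell is isolated at this scale", call. = FALSE)
  if (any(isolated))
    warning(sprintf("%d isolated cell(s) (no contiguous neighbours)",
                    sum(isolated)))
  w <- lapply(seq_len(n), function(i) {
    k <- length(nb[[i]])
    if (k == 0L) numeric(0)
    else if (style == "row") rep(1 / k, k)
    else rep(1, k)
  })
  structure(list(n = n, ids = cells$cell_id, neighbors = nb, weights = w,
                 style = style, isolated = isolated),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, style = %s, avg links = %.2f\n",
              x$n, x$style, mean(lengths(x$neighbors))))
  if (any(x$isolated))
    cat(sprintf("  %d isolated cell(s)\n", sum(x$isolated)))
  invisible(x)
}

#' Dense matrix form of a spatial weights object
#'
#' @param w a `spatial_weights`.
#' @return An `n x n` numeric matrix.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  m <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n))
    m[i, w$neighbors[[i]]] <- w$weights[[i]]
  m
}

#' Export weights as a sparse triplet table
#'
#' @param w a `spatial_weights`.
#' @param path optional CSV path; when given the table is written there.
#' @return Data frame with columns `i`, `j`, `w` (cell ids).
#' @export
weights_triplets <- function(w, path = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  rows <- do.call(rbind, lapply(seq_len(w$n), function(i) {
    if (!length(w$neighbors[[i]])) return(NULL)
    data.frame(i = w$ids[i], j = w$ids[w$neighbors[[i]]], w = w$weights[[i]])
  }))
  if (is.null(rows)) rows <- data.frame(i = integer(), j = integer(), w = numeric())
  if (!is.null(path)) utils::write.csv(rows, path, row.names = FALSE)
  rows
}

# sum of all weights S0
weights_s0 <- function(w) sum(unlist(w$weights))

# spatial lag of a vector
spatial_lag <- function(w, z) {
  vapply(seq_len(w$n), function(i) {
    if (!length(w$neighbors[[i]])) 0 else sum(w$weights[[i]] * z[w$neighbors[[i]]])
  }, numeric(1))
}
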