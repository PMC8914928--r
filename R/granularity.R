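#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when it is at least as good in every objective and
#' strictly better in at least one, with "better" read per objective from
#' `senses` (`"max"` or `"min"`).
#'
#' @param a,b numeric objective vectors of equal length.
#' @param senses character vector of `"max"`/`"min"`, one per objective.
#' @return Logical scalar.
#' @examples
#' dominates(c(0.5, 1.0), c(0.3, 2.0), c("max", "min"))  # TRUE
#' @export
dominates <- function(a, b, senses = c("max", "min")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 1)
    stop("objective vectors must have equal positive length", call. = FALSE)
  if (length(senses) != length(a))
    stop("one sense per objective required", call. = FALSE)
  if (any(is.na(a)) || any(is.na(b)))
    stop("invalid objective: NaN/NA in objective vector", call. = FALSE)
  senses <- match.arg(senses, c("max", "min"), several.ok = TRUE)
  # orient so larger is better everywhere
  s <- ifelse(senses == "max", 1, -1)
  aa <- s * a; bb <- s * b
  all(aa >= bb) && any(aa > bb)
}

#' Non-dominated (Pareto) sorting of candidates
#'
#' Iteratively peels non-dominated fronts: frontier 1 is the set dominated
#' by no candidate; remove it and repeat. Every candidate receives a
#' `frontier_rank`; the rank-1 set is the Pareto-optimal set. With the two
#' granularity criteria (Global Moran's I to maximise, CV of local Moran's I
#' to minimise) rank 1 holds the optimal areal-unit scales.
#'
#' @param objectives numeric matrix (candidates in rows, objectives in
#'   columns) or data frame.
#' @param senses `"max"`/`"min"` per objective column.
#' @return Object of class `pareto_ranking`: list with `rank` (integer per
#'   candidate), `frontiers` (list of row-index vectors), `optimal`
#'   (rank-1 row indices).
#' @export
pareto_rank <- function(objectives, senses = c("max", "min")) {
  m <- as.matrix(objectives)
  if (nrow(m) < 1) stop("need at least one candidate", call. = FALSE)
  if (any(is.na(m)))
    stop("invalid objective: NaN/NA in candidate set", call. = FALSE)
  n <- nrow(m)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && dominates(m[j, ], m[i, ], senses), logical(1)))
    }, logical(1))
    if (!any(nd)) stop("dominance cycle detected (should be impossible)")
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  frontiers <- split(seq_len(n), rank)
  structure(list(rank = rank, frontiers = unname(frontiers),
                 optimal = which(rank == 1L), senses = senses),
            class = "pareto_ranking")
}

#' @export
print.pareto_ranking <- function(x, ...) {
  cat(sprintf("<pareto_ranking> %d candidates in %d frontier(s); rank-1: %s\n",
              length(x$rank), max(x$rank),
              paste(x$optimal, collapse = ", ")))
  invisible(x)
}

#' Evaluate candidate areal-unit scales and select the optimal granularity
#'
#' The multicriteria areal-unit selection procedure: for each candidate
#' hexagon side length the sensor points are aggregated into a hexagonal
#' layer, first-order contiguity weights are built, and the scale is scored
#' by its Global Moran's I (GM, maximise) and the coefficient of variation
#' of the Local Moran's I values (LMCV, minimise). Candidates are then
#' Pareto-ranked on the two conflicting criteria; the rank-1 frontier is the
#' set of optimal spatial granularities. Scales yielding fewer than 3
#' non-empty cells, an all-isolated graph, or constant cell values are
#' dropped with a warning.
#'
#' @param data a planar-km [point_data()] (project first if in lon/lat).
#' @param scales numeric vector of candidate hexagon side lengths (km),
#'   e.g. `c(100, 200, 300, 400, 500)` for a continental study.
#' @param statistic cell aggregation statistic (default `"mean"`).
#' @param min_count minimum points per non-empty cell.
#' @param style weights style, `"row"` (default) or `"binary"`.
#' @param permutations permutations for the pseudo-significance tests.
#' @param seed integer seed driving all permutation randomness.
#' @param bbox optional bounding box; defaults to the data bbox.
#' @return Object of class `granularity_eval`: data frame `scale, GM, LMCV,
#'   n_cells, p_pseudo, frontier_rank` (attribute `optimal` holds the
#'   rank-1 scales; attribute `dropped` the scales that failed).
#' @examples
#' pd <- simulate_field(field_spec(n_points = 150, range_km = 120, seed = 4))
#' ev <- evaluate_scales(pd, c(40, 80, 160), permutations = 99, seed = 4)
#' ev
#' @export
evaluate_scales <- function(data, scales, statistic = "mean", min_count = 1L,
                            style = c("row", "binary"), permutations = 999,
                            seed = 1L, bbox = NULL) {
  stopifnot(inherits(data, "point_data"))
  if (data$crs != "planar-km")
    stop("evaluate_scales() works in a planar km frame; see project_to_planar()",
         call. = FALSE)
  style <- match.arg(style)
  if (length(scales) < 1) stop("no candidate scales", call. = FALSE)
  if (is.null(bbox)) bbox <- bbox_of(data)
  rows <- list(); dropped <- character(0)
  for (s in scales) {
    res <- tryCatch({
      layer <- make_hex_grid(bbox, side = s)
      layer <- hex_aggregate(data, layer, statistic = statistic,
                             min_count = min_count)
      cells <- hex_cells(layer)
      if (nrow(cells) < 3)
        stop(sprintf("only %d non-empty cell(s)", nrow(cells)), call. = FALSE)
      w <- contiguity_weights(layer, style = style)
      gm <- global_moran(cells$value, w, permutations = permutations,
                         seed = seed)
      li <- local_moran(cells$value, w, permutations = 0, seed = seed)
      data.frame(scale = s, GM = gm$I, LMCV = cv_local(li),
                 n_cells = nrow(cells), p_pseudo = gm$p_pseudo)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("scale %g km dropped: %s", s, conditionMessage(res)),
              call. = FALSE)
      dropped <- c(dropped, sprintf("%g: %s", s, conditionMessage(res)))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    stop("no candidate scale survived evaluation", call. = FALSE)
  cand <- do.call(rbind, rows)
  pr <- pareto_rank(cand[, c("GM", "LMCV")], senses = c("max", "min"))
  cand$frontier_rank <- pr$rank
  structure(cand, class = c("granularity_eval", "data.frame"),
            optimal = cand$scale[pr$rank == 1L], dropped = dropped,
            style = style, permutations = permutations, seed = seed)
}

#' @export
print.granularity_eval <- function(x, ...) {
  cat("Candidate areal-unit scales (GM: Global Moran's I, maximise;",
      "LMCV: CV of local Moran's I, minimise)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Pareto-optimal scale(s): %s km\n",
              paste(attr(x, "optimal"), collapse = ", ")))
  if (length(attr(x, "dropped")))
    cat("Dropped scales:", paste(attr(x, "dropped"), collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.granularity_eval <- function(object, ...) {
  cat(sprintf("%d candidate scale(s), %d frontier(s); optimal: %s km\n",
              nrow(object), max(object$frontier_rank),
              paste(attr(object, "optimal"), collapse = ", ")))
  invisible(object)
}

#' Trade-off chart of the granularity criteria
#'
#' Plots each candidate scale in the (GM, LMCV) objective plane, rank-1
#' candidates highlighted. For display the LMCV axis can be min--max scaled
#' into the span of the GM values (a monotone per-objective rescaling that
#' cannot change dominance); the ranking itself always uses raw objectives.
#'
#' @param x a `granularity_eval`.
#' @param normalize logical; rescale LMCV into the GM range for display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.granularity_eval <- function(x, normalize = FALSE, ...) {
  lmcv <- x$LMCV
  ylab <- "CV of Local Moran's I"
  if (normalize && diff(range(lmcv)) > 0) {
    lmcv <- (lmcv - min(lmcv)) / diff(range(lmcv)) *
      diff(range(x$GM)) + min(x$GM)
    ylab <- paste(ylab, "(min-max scaled to GM range)")
  }
  opt <- x$frontier_rank == 1L
  graphics::plot(x$GM, lmcv, pch = ifelse(opt, 19, 1),
                 col = ifelse(opt, "red", "black"),
                 xlab = "Global Moran's I", ylab = ylab, ...)
  graphics::text(x$GM, lmcv, labels = paste0(x$scale, " km"), pos = 3,
                 cex = 0.8)
  invisible(x)
}
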