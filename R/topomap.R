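#' Topographic interpolation of a channel map
#'
#' Inverse-distance-weighted interpolation (power 2) of per-electrode
#' values over a 2-D azimuthal-equidistant projection of the scalp
#' (vertex at the origin). The interpolant is exact at electrode sites;
#' grid points outside the convex hull of the electrodes are masked.
#' Intended for the 4-types x 3-windows figure layout, with colour
#' limits symmetric about 0 (maximum ERD red, maximum ERS blue).
#'
#' @param values Named numeric vector, one value per electrode label.
#' @param positions Positions data frame ([montage_1020()]); labels
#'   without built-in positions must be supplied here.
#' @param grid_n Grid resolution per axis.
#' @param power IDW exponent.
#' @return List of class `topographic_frame`: `x`, `y` (grid axes),
#'   `grid` (matrix, `NA` outside the hull), `positions` (electrodes
#'   used, with their values).
#' @export
topomap <- function(values, positions = NULL, grid_n = 67, power = 2) {
  labs <- names(values)
  if (is.null(labs)) stop("values must be named by electrode label")
  if (length(values) < 4L)
    stop("need at least 4 electrodes with positions")
  if (is.null(positions)) positions <- montage_1020(labs)
  miss <- setdiff(labs, positions$label)
  if (length(miss) > 0L)
    stop("no position for electrode label(s): ",
         paste(miss, collapse = ", "))
  pos <- positions[match(labs, positions$label), ]
  px <- pos$px; py <- pos$py
  ax <- seq(min(px), max(px), length.out = grid_n)
  ay <- seq(min(py), max(py), length.out = grid_n)
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  grid <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    inside <- point_in_polygon(ax[i], ay, hx, hy)
    for (j in which(inside)) {
      d2 <- (px - ax[i])^2 + (py - ay[j])^2
      if (any(d2 < 1e-18)) {
        grid[i, j] <- values[which.min(d2)]
      } else {
        w <- d2^(-power / 2)
        grid[i, j] <- sum(w * values) / sum(w)
      }
    }
  }
  pos$value <- as.numeric(values)
  structure(list(x = ax, y = ay, grid = grid, positions = pos),
            class = "topographic_frame")
}

# Even-odd ray-casting point-in-polygon test, vectorized over y, with a
# symmetric boundary rule: points within `eps` of a hull edge count as
# inside, so knife-edge grid nodes classify identically under left-right
# mirroring of the montage.
point_in_polygon <- function(x0, ys, hx, hy, eps = 1e-9) {
  n <- length(hx)
  inside <- rep(FALSE, length(ys))
  boundary <- rep(FALSE, length(ys))
  j <- n
  for (i in seq_len(n)) {
    xi <- hx[i]; yi <- hy[i]; xj <- hx[j]; yj <- hy[j]
    crosses <- ((yi > ys) != (yj > ys)) &
      (x0 < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # distance from (x0, ys) to segment (xi,yi)-(xj,yj)
    vx <- xj - xi; vy <- yj - yi
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((x0 - xi) * vx + (ys - yi) * vy) / L2))
         else 0
    d2 <- (x0 - (xi + t * vx))^2 + (ys - (yi + t * vy))^2
    boundary <- boundary | d2 <= eps^2
    j <- i
  }
  inside | boundary
}

#' Value of a topographic frame at a location
#'
#' @param frame A [topomap()] result.
#' @param px,py Projected coordinates.
#' @return Interpolated value at the nearest grid node.
#' @export
topomap_at <- function(frame, px, py) {
  i <- which.min(abs(frame$x - px))
  j <- which.min(abs(frame$y - py))
  frame$grid[i, j]
}

#' Plot a set of topographic frames (types x windows)
#'
#' Renders the per-band figure layout: one row per performance type, one
#' column per pre-shot window, diverging colour scale symmetric about 0
#' (maximum ERD red, maximum ERS blue). Requires ggplot2.
#'
#' @param frames Named list of `topographic_frame`s
#'   (`Type|interval` keys).
#' @param limit Colour limit; defaults to the largest absolute value.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_topomaps <- function(frames, limit = NULL, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_topomaps requires the ggplot2 package")
  dfs <- lapply(names(frames), function(k) {
    f <- frames[[k]]
    g <- expand.grid(px = f$x, py = f$y)
    g$value <- as.vector(f$grid)
    g$panel <- k
    g
  })
  df <- do.call(rbind, dfs)
  df <- df[!is.na(df$value), ]
  if (is.null(limit)) limit <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel, ncol = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-limit, limit),
                                  name = "ERD/ERS %") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
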