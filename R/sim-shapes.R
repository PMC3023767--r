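#' Simulate cell-outline polygons with known area and perimeter
#'
#' Generates closed simple polygons of three kinds, together with their exact
#' area (shoelace) and perimeter (edge sum), as test inputs for
#' [shape_metrics()].
#'
#' @param kind one of `"circle_ngon"` (regular n-gon approximating a circle),
#'   `"rectangle"`, `"star"` (alternating-radius star polygon).
#' @param params named list:
#'   `circle_ngon` needs `r` and `n`; `rectangle` needs `width` and `height`;
#'   `star` needs `n_arms`, `r_outer`, `r_inner`.
#' @return list with `vertices` (two-column matrix, not repeating the first
#'   vertex), `area`, `perimeter`, `kind`.
#' @export
#' @examples
#' simulate_shapes("rectangle", list(width = 2, height = 4))[c("area", "perimeter")]
simulate_shapes <- function(kind = c("circle_ngon", "rectangle", "star"),
                            params = list()) {
  kind <- match.arg(kind)
  v <- switch(
    kind,
    circle_ngon = {
      r <- params$r %||% 1; n <- params$n %||% 64L
      check_scalar_pos(r, "r"); check_scalar_pos(n, "n")
      if (n < 3) abort2("polygon needs >= 3 vertices", "acidhesion_bad_arg")
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(r * cos(th), r * sin(th))
    },
    rectangle = {
      w <- params$width %||% 1; h <- params$height %||% 1
      check_scalar_pos(w, "width"); check_scalar_pos(h, "height")
      cbind(c(0, w, w, 0), c(0, 0, h, h))
    },
    star = {
      k <- params$n_arms %||% 5L
      ro <- params$r_outer %||% 1; ri <- params$r_inner %||% 0.4
      check_scalar_pos(ro, "r_outer"); check_scalar_pos(ri, "r_inner")
      if (k < 3) abort2("star needs >= 3 arms", "acidhesion_bad_arg")
      if (ri >= ro) {
        abort2(paste0("star needs r_inner < r_outer (otherwise the ",
                      "parameterization self-intersects)"),
               "acidhesion_bad_arg")
      }
      th <- pi / 2 + 2 * pi * (0:(2 * k - 1)) / (2 * k)
      rad <- rep(c(ro, ri), k)
      cbind(rad * cos(th), rad * sin(th))
    }
  )
  colnames(v) <- c("x", "y")
  list(vertices = v,
       area = abs(polygon_area_signed(v)),
       perimeter = polygon_perimeter(v),
       kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed shoelace area; vertices as two-column matrix, first vertex NOT
# repeated at the end
polygon_area_signed <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

# TRUE when any two non-adjacent edges properly intersect (simple-polygon
# check; O(n^2) vectorized over edge pairs)
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1L & !(i == 1L & j == n)
  }), arr.ind = TRUE)
  if (!nrow(pairs)) return(FALSE)
  i <- pairs[, 1]; j <- pairs[, 2]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  d2 <- cross(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- cross(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  d4 <- cross(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}
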