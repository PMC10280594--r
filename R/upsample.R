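#' Bilinear interpolation at arbitrary query points
#'
#' Evaluates the classical two-pass linear interpolation of a 2-D grid at
#' real-valued query coordinates: first along x between the two bracketing
#' columns, then along y between the two intermediate values. Grid nodes are
#' registered at integer coordinates `0 .. ncol-1` (x) and `0 .. nrow-1`
#' (y), so querying a node reproduces its value exactly.
#'
#' @param grid numeric matrix (rows = y, columns = x), at least 2 x 2.
#' @param x,y query coordinates (vectors of equal length) in grid units.
#' @return numeric vector of interpolated values.
#' @examples
#' g <- rbind(c(10, 30), c(20, 40))   # f(Q11)=10, f(Q21)=20, f(Q12)=30, f(Q22)=40
#' interp_bilinear(g, 0.5, 0.5)       # 25, the mean of the four corners
#' @export
interp_bilinear <- function(grid, x, y) {
  stopifnot(is.matrix(grid), nrow(grid) >= 2, ncol(grid) >= 2,
            length(x) == length(y))
  x <- pmin(pmax(x, 0), ncol(grid) - 1)
  y <- pmin(pmax(y, 0), nrow(grid) - 1)
  x0 <- pmin(floor(x), ncol(grid) - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nrow(grid) - 2); y1 <- y0 + 1
  tx <- x - x0; ty <- y - y0
  # interpolate along x at both bracketing rows (R1, R2), then along y
  r1 <- (1 - tx) * grid[cbind(y0 + 1, x0 + 1)] + tx * grid[cbind(y0 + 1, x1 + 1)]
  r2 <- (1 - tx) * grid[cbind(y1 + 1, x0 + 1)] + tx * grid[cbind(y1 + 1, x1 + 1)]
  (1 - ty) * r1 + ty * r2
}

#' Bilinear upsampling of a 2-D grid
#'
#' Resamples `grid` to `out_h` x `out_w` by separable linear interpolation.
#' The default pixel-centre convention (`align_corners = FALSE`, the
#' convention used inside the segmentation head) maps output pixel centres
#' to input pixel centres; `align_corners = TRUE` registers grid corners to
#' grid corners instead. Output values always lie within the range of the
#' input, and resampling to the input size reproduces the input exactly.
#'
#' @param grid numeric matrix with at least 2 rows and columns.
#' @param out_h,out_w output size in pixels, `>= 1`.
#' @param align_corners registration convention, see Details.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
upsample_bilinear <- function(grid, out_h, out_w, align_corners = FALSE) {
  if (!is.matrix(grid) || nrow(grid) < 2 || ncol(grid) < 2)
    stop("`grid` must be a matrix with at least 2 rows and 2 columns")
  stopifnot(out_h >= 1, out_w >= 1)
  x <- array(as.numeric(grid), dim = c(nrow(grid), ncol(grid), 1L, 1L))
  y <- cpp_bilinear_fw(x, as.integer(out_h), as.integer(out_w),
                       isTRUE(align_corners))
  matrix(y, nrow = out_h, ncol = out_w)
}
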