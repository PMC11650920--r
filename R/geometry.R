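#' System geometry of the modelled habitat
#'
#' Describes the enclosed freshwater habitat as a patch grid: a 20 m2
#' system of 500 patches of 20 x 20 cm, of which a fixed fraction are
#' vegetated and food-bearing (default 10%, i.e. 50 food patches).
#'
#' @param area Habitat area in m2.
#' @param n_patches Number of patches.
#' @param vegetated_ratio Fraction of patches that are vegetated;
#'   `n_patches * vegetated_ratio` must be a whole number.
#' @param grid_dim Integer vector `c(rows, cols)` with
#'   `rows * cols == n_patches`.
#' @return An object of class `system_geometry`: a list with elements
#'   `area`, `n_patches`, `vegetated_ratio`, `n_vegetated`, `patch_area`
#'   (m2) and `grid_dim`.
#' @examples
#' geom <- system_geometry()
#' geom$n_vegetated  # 50
#' geom$patch_area   # 0.04 m2
#' @export
system_geometry <- function(area = 20, n_patches = 500L,
                            vegetated_ratio = 0.1,
                            grid_dim = c(25L, 20L)) {
  stopifnot(is.numeric(area), length(area) == 1L, is.finite(area), area > 0)
  n_patches <- as.integer(n_patches)
  stopifnot(n_patches >= 1L, is.numeric(vegetated_ratio),
            vegetated_ratio >= 0, vegetated_ratio <= 1)
  n_veg <- n_patches * vegetated_ratio
  if (abs(n_veg - round(n_veg)) > 1e-9)
    stop("n_patches * vegetated_ratio must be a whole number", call. = FALSE)
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 2L || prod(grid_dim) != n_patches)
    stop("grid_dim must multiply to n_patches", call. = FALSE)
  structure(list(area = area, n_patches = n_patches,
                 vegetated_ratio = vegetated_ratio,
                 n_vegetated = as.integer(round(n_veg)),
                 patch_area = area / n_patches,
                 grid_dim = grid_dim),
            class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf("system_geometry: %.3g m2, %d patches (%d vegetated), %.3g m2 each\n",
              x$area, x$n_patches, x$n_vegetated, x$patch_area))
  invisible(x)
}
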