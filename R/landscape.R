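## Landscape: the 20 m2 habitat as a grid of patches, 10% vegetated and
## food-bearing, with daily food renewal and within-day depletion.

#' Initialise the patch landscape
#'
#' Lays out the habitat grid (default 25 x 20 = 500 patches) and places
#' the vegetated, food-bearing patches uniformly at random. Vegetated
#' positions are fixed for the rest of a simulation. All food stocks
#' start at zero until the first renewal.
#'
#' @param geometry A [system_geometry()].
#' @param seed Optional integer seed for the vegetated layout (the
#'   caller's RNG stream is used when `NULL`).
#' @return An object of class `landscape`: a list with `geometry`,
#'   `habitat` (logical, `TRUE` = vegetated), `food` (g per patch),
#'   `row`, `col`, `vegetated_idx` and `day_of_year`.
#' @examples
#' ls <- init_landscape(seed = 1)
#' sum(ls$habitat)  # 50 vegetated food patches
#' @export
init_landscape <- function(geometry = system_geometry(), seed = NULL) {
  stopifnot(inherits(geometry, "system_geometry"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- geometry$n_patches
  habitat <- rep(FALSE, n)
  if (geometry$n_vegetated > 0L)
    habitat[sample.int(n, geometry$n_vegetated)] <- TRUE
  nr <- geometry$grid_dim[1]
  idx <- seq_len(n)
  structure(list(geometry = geometry,
                 habitat = habitat,
                 food = numeric(n),
                 row = ((idx - 1L) %% nr) + 1L,
                 col = ((idx - 1L) %/% nr) + 1L,
                 vegetated_idx = which(habitat),
                 day_of_year = 1L),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d patches (%d vegetated), total food %.4g g, day %d\n",
              x$geometry$n_patches, length(x$vegetated_idx),
              sum(x$food), x$day_of_year))
  invisible(x)
}

#' Renew daily food stocks
#'
#' Resets every vegetated patch's food stock to the day's food density
#' (the scenario's value for the current month). Renewal is a daily
#' reset, not an accumulation: the scenario supplies a daily production
#' rate. With `carry_over = TRUE` unconsumed food is retained and the
#' day's production is added instead. Nonvegetated patches never hold
#' food.
#'
#' @param landscape A `landscape`.
#' @param food_density Food per vegetated patch for the day,
#'   g patch-1 d-1 (>= 0). Usually
#'   `scenario$monthly_food_per_patch[month_of_day(day)]`.
#' @param day Day of year to stamp on the state.
#' @param carry_over Retain unconsumed stock (default `FALSE`, reset).
#' @return The updated `landscape`.
#' @export
renew_food <- function(landscape, food_density, day = landscape$day_of_year,
                       carry_over = FALSE) {
  stopifnot(inherits(landscape, "landscape"),
            is.finite(food_density), food_density >= 0)
  if (carry_over) {
    landscape$food[landscape$vegetated_idx] <-
      landscape$food[landscape$vegetated_idx] + food_density
  } else {
    landscape$food[landscape$vegetated_idx] <- food_density
  }
  landscape$day_of_year <- as.integer(day)
  landscape
}

#' Consume food from one patch
#'
#' Takes `min(demand, stock)` from the patch. Consuming from a
#' nonvegetated (foodless) patch returns zero; stocks never go
#' negative.
#'
#' @param landscape A `landscape`.
#' @param patch_index Patch index.
#' @param demand Demanded mass, g (>= 0).
#' @return A list with `taken` (g actually consumed) and `landscape`
#'   (updated state).
#' @examples
#' ls <- renew_food(init_landscape(seed = 1), 0.02)
#' consume(ls, ls$vegetated_idx[1], 0.005)$taken
#' @export
consume <- function(landscape, patch_index, demand) {
  stopifnot(inherits(landscape, "landscape"), demand >= 0,
            patch_index >= 1L, patch_index <= landscape$geometry$n_patches)
  taken <- min(demand, landscape$food[patch_index])
  landscape$food[patch_index] <- landscape$food[patch_index] - taken
  list(taken = taken, landscape = landscape)
}

#' Export or import a landscape layout as delimited text
#'
#' Writes/reads the fixed patch layout (index, row, col, habitat) as a
#' CSV, so layouts can be frozen as reproducible fixtures.
#'
#' @param landscape A `landscape`.
#' @param path File path.
#' @param geometry Geometry to attach on import (must match the row
#'   count).
#' @return `write_landscape_layout()` invisibly returns `path`;
#'   `read_landscape_layout()` returns a `landscape` with zero food.
#' @export
write_landscape_layout <- function(landscape, path) {
  stopifnot(inherits(landscape, "landscape"))
  utils::write.csv(data.frame(index = seq_along(landscape$habitat),
                              row = landscape$row, col = landscape$col,
                              habitat = ifelse(landscape$habitat,
                                               "vegetated", "nonvegetated")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_layout
#' @export
read_landscape_layout <- function(path, geometry = system_geometry()) {
  x <- utils::read.csv(path)
  need <- c("index", "row", "col", "habitat")
  if (!all(need %in% names(x)))
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- x[order(x$index), ]
  if (nrow(x) != geometry$n_patches)
    stop("layout row count does not match geometry", call. = FALSE)
  habitat <- x$habitat == "vegetated"
  if (sum(habitat) != geometry$n_vegetated)
    stop("layout vegetated count does not match geometry", call. = FALSE)
  structure(list(geometry = geometry, habitat = habitat,
                 food = numeric(geometry$n_patches),
                 row = as.integer(x$row), col = as.integer(x$col),
                 vegetated_idx = which(habitat), day_of_year = 1L),
            class = "landscape")
}
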