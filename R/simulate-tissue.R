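# Synthetic tissue specimens: an indexed label map plus a nucleus table,
# with every geometric quantity known by construction so the morphometry
# features can be checked against closed forms.

tissue_classes <- c("background", "tumor", "stroma", "necrosis", "fat")

#' Construct a tissue label map
#'
#' @param grid Integer matrix of class indices (rows = y, columns = x).
#' @param palette Named integer vector mapping class name to index; must
#'   cover every index used in `grid`.
#' @param pixel_size Pixel edge length in micrometres.
#' @return A `tissue_map`.
#' @export
tissue_map <- function(grid,
                       palette = setNames(0:4, tissue_classes),
                       pixel_size = 0.5) {
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  used <- unique(as.vector(grid))
  if (!all(used %in% palette)) {
    abort("grid contains indices absent from the palette")
  }
  structure(list(grid = grid, palette = palette, pixel_size = pixel_size),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("<tissue_map> %d x %d px at %.3g um/px\n",
              ncol(x$grid), nrow(x$grid), x$pixel_size))
  tab <- table(factor(as.vector(x$grid), levels = x$palette,
                      labels = names(x$palette)))
  for (cl in names(tab)) cat(sprintf("  %s: %d px\n", cl, tab[[cl]]))
  invisible(x)
}

#' Simulate a tissue specimen: label map plus nucleus table
#'
#' Rectangular class regions are painted onto a background canvas; painting
#' a pixel already owned by a different foreground class is an error
#' (overlapping same-class rectangles are allowed). Nuclei are then placed
#' uniformly at pixel centres of their class region, with morphology and
#' stain statistics drawn from the per-class specification. A degenerate
#' spread (sd = 0) yields exact feature values, which the tests exploit.
#'
#' @param width,height Map size in pixels.
#' @param layout Tibble with columns `class`, `x`, `y`, `w`, `h`
#'   (0-based top-left corner and size, in pixels).
#' @param nuclei Tibble with columns `class`, `n`, `area_mean` and optional
#'   `area_sd`, `circularity_mean`, `circularity_sd`, `eosin_mean`,
#'   `hematoxylin_mean`, `stain_sd`, `lymphocyte_prob`.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed; fixed seed reproduces the specimen exactly.
#' @return List with `map` (a `tissue_map`) and `nuclei` (a tibble with
#'   columns id, x, y, area, diameter, circularity, eosin_mean, eosin_var,
#'   hematoxylin_mean, hematoxylin_var, cell_type).
#' @export
simulate_tissue_specimen <- function(width, height, layout, nuclei = NULL,
                                     pixel_size = 0.5, seed = 1L) {
  layout <- as_tibble(layout)
  stopifnot(all(c("class", "x", "y", "w", "h") %in% names(layout)))
  bad <- setdiff(layout$class, tissue_classes)
  if (length(bad) > 0) abort(paste0("unknown tissue class: ", paste(bad, collapse = ", ")))

  palette <- setNames(0:4, tissue_classes)
  grid <- matrix(0L, nrow = height, ncol = width)
  owner <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_len(nrow(layout))) {
    cls <- palette[[layout$class[i]]]
    rows <- (layout$y[i] + 1):(layout$y[i] + layout$h[i])
    cols <- (layout$x[i] + 1):(layout$x[i] + layout$w[i])
    if (min(rows) < 1 || max(rows) > height || min(cols) < 1 || max(cols) > width) {
      abort("layout region extends beyond the map")
    }
    prev <- owner[rows, cols]
    if (any(prev != 0L & prev != cls)) {
      abort("overlapping layout regions with conflicting classes")
    }
    owner[rows, cols] <- cls
    grid[rows, cols] <- cls
  }
  map <- tissue_map(grid, palette, pixel_size)

  nuc <- with_seed(seed, simulate_nuclei(map, nuclei))
  list(map = map, nuclei = nuc)
}

simulate_nuclei <- function(map, spec) {
  empty <- tibble(
    id = character(), x = numeric(), y = numeric(), area = numeric(),
    diameter = numeric(), circularity = numeric(),
    eosin_mean = numeric(), eosin_var = numeric(),
    hematoxylin_mean = numeric(), hematoxylin_var = numeric(),
    cell_type = character()
  )
  if (is.null(spec) || nrow(spec) == 0) return(empty)
  spec <- as_tibble(spec)
  stopifnot(all(c("class", "n", "area_mean") %in% names(spec)))
  defaults <- list(area_sd = 0, circularity_mean = 0.85, circularity_sd = 0,
                   eosin_mean = 0.5, hematoxylin_mean = 0.6, stain_sd = 0,
                   lymphocyte_prob = 0)
  for (nm in names(defaults)) {
    if (!nm %in% names(spec)) spec[[nm]] <- defaults[[nm]]
  }

  palette <- map$palette
  rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(spec))) {
    cls_idx <- palette[[spec$class[i]]]
    px <- which(map$grid == cls_idx)
    n <- spec$n[i]
    if (n == 0) next
    if (length(px) == 0) {
      abort(sprintf("no pixels of class '%s' to place nuclei in", spec$class[i]))
    }
    pick <- px[sample.int(length(px), n, replace = TRUE)]
    # pixel centres in 0-based continuous coordinates
    r <- (pick - 1) %% nrow(map$grid) + 1
    cl <- (pick - 1) %/% nrow(map$grid) + 1
    area <- pmax(rnorm(n, spec$area_mean[i], spec$area_sd[i]), 0.5)
    circ <- pmin(pmax(rnorm(n, spec$circularity_mean[i], spec$circularity_sd[i]), 0), 1)
    rows[[i]] <- tibble(
      id = sprintf("N%05d", counter + seq_len(n)),
      x = cl - 0.5, y = r - 0.5,
      area = area,
      diameter = 2 * sqrt(area / pi),
      circularity = circ,
      eosin_mean = rnorm(n, spec$eosin_mean[i], spec$stain_sd[i]),
      eosin_var = abs(rnorm(n, 0.01, spec$stain_sd[i] / 10)),
      hematoxylin_mean = rnorm(n, spec$hematoxylin_mean[i], spec$stain_sd[i]),
      hematoxylin_var = abs(rnorm(n, 0.01, spec$stain_sd[i] / 10)),
      cell_type = ifelse(runif(n) < spec$lymphocyte_prob[i], "lymphocyte", "other")
    )
    counter <- counter + n
  }
  bind_rows(rows)
}

#' Write / read a tissue map as an indexed PNG with a JSON palette sidecar
#'
#' The label grid is stored as an 8-bit grayscale PNG whose pixel value is
#' the class index; the sidecar records the index-to-class mapping and the
#' pixel size, so the pair round-trips exactly.
#'
#' @param map A `tissue_map`.
#' @param path PNG path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tissue_map <- function(map, path) {
  stopifnot(inherits(map, "tissue_map"))
  png::writePNG(map$grid / 255, path)
  jsonlite::write_json(
    list(palette = as.list(setNames(map$palette, names(map$palette))),
         pixel_size = map$pixel_size),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tissue_map
#' @export
read_tissue_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  grid <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  side <- jsonlite::read_json(paste0(path, ".json"))
  palette <- setNames(as.integer(unlist(side$palette)), names(side$palette))
  tissue_map(grid, palette, side$pixel_size)
}
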