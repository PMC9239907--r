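# Interpretable histopathological embedding: tissue-type region properties,
# composition features, and nuclear morphometry aggregates.
#
# Conventions, applied throughout and exercised by the property tests:
#  - shape descriptors come from the ellipse with matching second central
#    moments of the pixel mask: with covariance eigenvalues l1 >= l2,
#    major = 4*sqrt(l1), minor = 4*sqrt(l2), eccentricity = sqrt(1 - l2/l1);
#  - connected components use 8-connectivity by default (configurable);
#  - perimeter is the count of exposed pixel edges times the pixel size;
#  - solidity is mask area over the pixel count of its convex hull;
#  - percentiles use linear interpolation between order statistics;
#  - areas are reported in um^2 and lengths in um.

# Label connected components of a logical mask. Pixels are vertices, edges
# connect 4- or 8-neighbours; components come from igraph.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  pos <- matrix(0L, nr * nc, 1)
  pos[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  cl <- (idx - 1L) %/% nr + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    r2 <- r + dr; c2 <- cl + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[nb] > 0L
    if (!any(hit)) next
    edges[[k]] <- rbind(pos[idx[ok]][hit], pos[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# Region properties of one logical mask (pixel units converted by ps).
mask_regionprops <- function(mask, ps) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) {
    return(list(area = 0, major_axis = 0, minor_axis = 0, eccentricity = 0,
                solidity = 0, perimeter = 0))
  }
  nr <- nrow(mask)
  y <- (idx - 1) %% nr
  x <- (idx - 1) %/% nr
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)

  # exposed pixel edges
  m <- mask
  up <- m & !rbind(FALSE, m[-nr, , drop = FALSE])
  dn <- m & !rbind(m[-1, , drop = FALSE], FALSE)
  lf <- m & !cbind(FALSE, m[, -ncol(m), drop = FALSE])
  rt <- m & !cbind(m[, -1, drop = FALSE], FALSE)
  perim_px <- sum(up) + sum(dn) + sum(lf) + sum(rt)

  solidity <- if (n <= 2) 1 else {
    pts <- cbind(x, y)
    hull <- grDevices::chull(pts)
    if (length(hull) < 3) 1 else {
      hx <- pts[hull, 1]; hy <- pts[hull, 2]
      inside <- pracma::inpolygon(x, y, hx, hy, boundary = TRUE)
      # convex pixel count: pixels of the bounding box whose centres fall
      # inside or on the hull polygon
      gx <- rep(seq(min(x), max(x)), times = max(y) - min(y) + 1)
      gy <- rep(seq(min(y), max(y)), each = max(x) - min(x) + 1)
      hull_n <- sum(pracma::inpolygon(gx, gy, hx, hy, boundary = TRUE))
      if (hull_n < n) 1 else n / hull_n
    }
  }

  list(
    area = n * ps^2,
    major_axis = 4 * sqrt(l1) * ps,
    minor_axis = 4 * sqrt(l2) * ps,
    eccentricity = if (l1 > 0) sqrt(1 - l2 / l1) else 0,
    solidity = solidity,
    perimeter = perim_px * ps
  )
}

#' Region properties of one tissue class
#'
#' Computes area, area fraction and shape properties (major/minor axis
#' length from the equal-second-moment ellipse, eccentricity, solidity,
#' perimeter) for both the union of all components of the class and its
#' largest connected component. An absent class yields all-zero features
#' and `absent = TRUE`.
#'
#' @param map A [tissue_map()].
#' @param class Class name present in the palette.
#' @param connectivity 4 or 8 (default) for connected components.
#' @return A one-row tibble.
#' @export
region_features <- function(map, class, connectivity = 8) {
  stopifnot(inherits(map, "tissue_map"))
  if (length(map$grid) == 0) abort("empty tissue map")
  if (!class %in% names(map$palette)) abort(paste0("class not in palette: ", class))
  ps <- map$pixel_size
  mask <- map$grid == map$palette[[class]]
  total_px <- length(mask)

  row <- function(scope, props, absent) {
    setNames(
      as.list(c(props$area, props$major_axis, props$minor_axis,
                props$eccentricity, props$solidity, props$perimeter)),
      paste0(scope, "_", c("area", "major_axis", "minor_axis",
                           "eccentricity", "solidity", "perimeter"))
    )
  }

  if (!any(mask)) {
    zero <- mask_regionprops(mask, ps)
    return(as_tibble(c(list(class = class, absent = TRUE, area_fraction = 0),
                       row("all", zero), row("lcc", zero))))
  }

  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  lcc <- lab == which.max(sizes)
  all_props <- mask_regionprops(mask, ps)
  lcc_props <- mask_regionprops(lcc, ps)
  as_tibble(c(
    list(class = class, absent = FALSE, area_fraction = sum(mask) / total_px),
    row("all", all_props), row("lcc", lcc_props)
  ))
}

#' Composition features of a tissue map
#'
#' All pairwise area ratios between the foreground tissue classes (missing
#' when the denominator class is absent), plus the patch-composition
#' entropy of tumor and of stroma: the Shannon entropy, in bits, of the
#' class-occupancy histogram pooled over fixed square patches that
#' intersect the target class.
#'
#' @param map A [tissue_map()].
#' @param patch Patch edge length in pixels for the entropy features.
#' @return A one-row tibble.
#' @export
composition_features <- function(map, patch = 64) {
  stopifnot(inherits(map, "tissue_map"))
  ps <- map$pixel_size
  classes <- setdiff(names(map$palette), "background")
  areas <- map_dbl(classes, function(cl) sum(map$grid == map$palette[[cl]]) * ps^2)
  names(areas) <- classes

  out <- as.list(setNames(areas, paste0("area_", classes)))
  for (a in classes) {
    for (b in classes) {
      if (a == b) next
      out[[paste0("ratio_", a, "_to_", b)]] <-
        if (areas[[b]] > 0) areas[[a]] / areas[[b]] else NA_real_
    }
  }
  out$entropy_tumor <- patch_entropy(map, "tumor", patch)
  out$entropy_stroma <- patch_entropy(map, "stroma", patch)
  as_tibble(out)
}

# Pooled class-occupancy entropy (bits) over patches intersecting `class`.
patch_entropy <- function(map, class, patch) {
  grid <- map$grid
  idx_target <- map$palette[[class]]
  nr <- nrow(grid); nc <- ncol(grid)
  counts <- numeric(length(map$palette))
  any_patch <- FALSE
  for (r0 in seq(1, nr, by = patch)) {
    for (c0 in seq(1, nc, by = patch)) {
      blk <- grid[r0:min(r0 + patch - 1, nr), c0:min(c0 + patch - 1, nc)]
      if (!any(blk == idx_target)) next
      any_patch <- TRUE
      counts <- counts + tabulate(match(as.vector(blk), map$palette),
                                  nbins = length(map$palette))
    }
  }
  if (!any_patch) return(NA_real_)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Assign a parent tissue class to each nucleus
#'
#' The parent is the class of the pixel containing the nucleus centroid (no
#' interpolation; a centroid exactly on a boundary pixel takes that pixel's
#' class). Background-parent nuclei are flagged `excluded` and dropped from
#' downstream aggregates.
#'
#' @param nuclei Nucleus table with 0-based pixel coordinates `x`, `y`.
#' @param map A [tissue_map()].
#' @return The nucleus table with `parent` and `excluded` columns added.
#' @export
assign_parents <- function(nuclei, map) {
  stopifnot(inherits(map, "tissue_map"))
  nuclei <- as_tibble(nuclei)
  if (nrow(nuclei) == 0) {
    nuclei$parent <- character()
    nuclei$excluded <- logical()
    return(nuclei)
  }
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  col <- floor(nuclei$x) + 1L
  row <- floor(nuclei$y) + 1L
  if (any(col < 1 | col > nc | row < 1 | row > nr)) {
    abort("nucleus centroid outside the map bounds")
  }
  cls_idx <- map$grid[cbind(row, col)]
  parent <- names(map$palette)[match(cls_idx, map$palette)]
  nuclei$parent <- parent
  nuclei$excluded <- parent == "background"
  nuclei
}

nuclear_measurements <- c("area", "diameter", "circularity",
                          "eosin_mean", "eosin_var",
                          "hematoxylin_mean", "hematoxylin_var")
nuclear_parents <- c("tumor", "stroma", "necrosis")
nuclear_celltypes <- c("all", "lymphocyte", "other")

#' Aggregate nuclear morphometry by tissue parent and cell type
#'
#' For each parent tissue in tumor/stroma/necrosis, each cell-type stratum
#' (all nuclei, lymphocytes, non-lymphocytes) and each measurement (area,
#' diameter, circularity, eosin and hematoxylin mean/variance), reports the
#' mean, variance and deciles 10-90; plus the lymphocyte fraction per
#' parent. Empty strata yield missing values.
#'
#' @param nuclei Nucleus table with parents assigned ([assign_parents()]).
#' @return A one-row tibble of named features.
#' @export
nuclear_aggregates <- function(nuclei) {
  nuclei <- as_tibble(nuclei)
  if (!"parent" %in% names(nuclei)) abort("assign parents before aggregating")
  nuclei <- dplyr::filter(nuclei, !.data$excluded)
  probs <- seq(0.1, 0.9, by = 0.1)

  out <- list()
  for (par in nuclear_parents) {
    sub_p <- dplyr::filter(nuclei, .data$parent == par)
    out[[paste0(par, "_lymphocyte_fraction")]] <- if (nrow(sub_p) > 0) {
      mean(sub_p$cell_type == "lymphocyte")
    } else {
      NA_real_
    }
    for (ct in nuclear_celltypes) {
      sub <- switch(ct,
        all = sub_p,
        lymphocyte = dplyr::filter(sub_p, .data$cell_type == "lymphocyte"),
        other = dplyr::filter(sub_p, .data$cell_type != "lymphocyte")
      )
      for (meas in nuclear_measurements) {
        key <- paste(par, ct, meas, sep = "_")
        vals <- sub[[meas]]
        if (length(vals) == 0) {
          out[[paste0(key, "_mean")]] <- NA_real_
          out[[paste0(key, "_var")]] <- NA_real_
          for (k in seq_along(probs)) {
            out[[sprintf("%s_p%02.0f", key, probs[k] * 100)]] <- NA_real_
          }
        } else {
          out[[paste0(key, "_mean")]] <- mean(vals)
          out[[paste0(key, "_var")]] <- if (length(vals) > 1) var(vals) else 0
          qs <- q_linear(vals, probs)
          for (k in seq_along(probs)) {
            out[[sprintf("%s_p%02.0f", key, probs[k] * 100)]] <- qs[k]
          }
        }
      }
    }
  }
  as_tibble(out)
}

#' Embed a specimen into the histopathological feature vector
#'
#' Concatenates composition features, per-class region features (tumor,
#' stroma, necrosis, fat), nuclear aggregates, and the relative specimen
#' size (foreground fraction of the grid). The feature registry is fixed
#' and ordered deterministically; every registered feature is present,
#' either with a value or as an explicit missing.
#'
#' @param map A [tissue_map()].
#' @param nuclei Nucleus table (parents are assigned internally if absent).
#' @param connectivity Connectivity for region components.
#' @param patch Patch size for entropy features.
#' @return A one-row tibble; attribute `registry_version` identifies the
#'   feature registry.
#' @export
embed_specimen <- function(map, nuclei, connectivity = 8, patch = 64) {
  stopifnot(inherits(map, "tissue_map"))
  if (!"parent" %in% names(nuclei)) nuclei <- assign_parents(nuclei, map)

  comp <- composition_features(map, patch = patch)
  regions <- map(setdiff(names(map$palette), "background"), function(cl) {
    rf <- region_features(map, cl, connectivity = connectivity)
    rf$absent <- as.numeric(rf$absent)
    stats_cols <- setdiff(names(rf), "class")
    setNames(rf[stats_cols], paste0(cl, "_", stats_cols))
  })
  agg <- nuclear_aggregates(nuclei)
  fg <- mean(map$grid != map$palette[["background"]])

  out <- bind_cols(c(
    list(tibble(relative_specimen_size = fg)),
    list(comp), regions, list(agg)
  ))
  attr(out, "registry_version") <- "1"
  out
}

#' Names of the histopathological feature registry
#'
#' @return Character vector of feature names in registry order.
#' @export
histo_feature_registry <- function() {
  blank <- tissue_map(matrix(c(0L, 1L, 2L, 3L, 4L, 0L), 2, 3), pixel_size = 1)
  nuc <- tibble(
    id = "N1", x = 0.5, y = 0.5, area = 1, diameter = 1, circularity = 1,
    eosin_mean = 0, eosin_var = 0, hematoxylin_mean = 0, hematoxylin_var = 0,
    cell_type = "other"
  )
  names(embed_specimen(blank, nuc))
}
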