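#' Traced mitochondrial outline
#'
#' One mitochondrion traced 1-3 times (repeated freehand tracings whose mean
#' area is used), with the imaged field area for density summaries.
#' Coordinates are calibrated nanometres.
#'
#' @param mito_id,image_id Identifiers.
#' @param tracings List of 1-3 two-column matrices (x, y in nm), each a
#'   simple (non-self-intersecting) polygon of >= 3 vertices.
#' @param field_area_um2 Area of the image field in square micrometres.
#' @return An `"outline_polygon"` object.
#' @export
outline_polygon <- function(mito_id, image_id, tracings, field_area_um2) {
  if (is.matrix(tracings)) tracings <- list(tracings)
  stopifnot(length(tracings) >= 1L, length(tracings) <= 3L,
            field_area_um2 > 0)
  tracings <- lapply(tracings, function(tr) {
    tr <- as.matrix(tr)
    if (ncol(tr) != 2L || nrow(tr) < 3L)
      stop("outline_polygon('", mito_id,
           "'): each tracing needs >= 3 (x, y) vertices")
    if (polygon_self_intersects(tr))
      stop("outline_polygon('", mito_id, "'): tracing is self-intersecting")
    if (shoelace(tr) == 0)
      stop("outline_polygon('", mito_id, "'): degenerate (zero-area) tracing")
    unname(tr)
  })
  structure(list(mito_id = as.character(mito_id),
                 image_id = as.character(image_id),
                 tracings = tracings, field_area_um2 = field_area_um2),
            class = "outline_polygon")
}

# signed shoelace area of a closed polygon given as open vertex ring
shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# proper-crossing test between non-adjacent edges; O(n^2), fine for tracings
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure edge
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Mitochondrial area from traced outlines
#'
#' Shoelace (surveyor's) area of each tracing, orientation-independent; the
#' returned value is the mean across the 1-3 repeated tracings, mirroring
#' triplicate manual tracing.
#'
#' @param outline An [outline_polygon()].
#' @return Area in nm^2.
#' @export
polygon_area <- function(outline) {
  stopifnot(inherits(outline, "outline_polygon"))
  mean(vapply(outline$tracings, function(tr) abs(shoelace(tr)), numeric(1)))
}

#' Maximal (Feret) diameter
#'
#' Maximum pairwise vertex distance of the first tracing - the caliper
#' diameter at the largest part of the mitochondrion.
#'
#' @param outline An [outline_polygon()].
#' @return Diameter in nm.
#' @export
max_diameter <- function(outline) {
  stopifnot(inherits(outline, "outline_polygon"))
  v <- outline$tracings[[1]]
  max(stats::dist(v))
}

#' Morphology classification thresholds
#'
#' The classifier uses the elongation statistic
#' `e = diameter / (2 sqrt(area / pi))` (Feret diameter over the diameter of
#' the equal-area circle): `e < frag_cut` is `fragmented`, `e >= long_cut` is
#' `long_tubular`, in between `short_tubular` (ties at `frag_cut` go up).
#'
#' @param frag_cut,long_cut Cutoffs, `frag_cut < long_cut`.
#' @return A named numeric vector of class `"morph_thresholds"`.
#' @export
morph_thresholds <- function(frag_cut = 1.3, long_cut = 2.5) {
  if (!is_number(frag_cut) || !is_number(long_cut) || frag_cut >= long_cut)
    stop("morph_thresholds: need frag_cut < long_cut")
  structure(c(frag_cut = frag_cut, long_cut = long_cut),
            class = "morph_thresholds")
}

#' Classify a mitochondrion by elongation
#'
#' @param area Area in nm^2.
#' @param diameter Feret diameter in nm.
#' @param thresholds A [morph_thresholds()].
#' @return `"fragmented"`, `"short_tubular"` or `"long_tubular"`.
#' @export
classify_morphology <- function(area, diameter,
                                thresholds = morph_thresholds()) {
  stopifnot(inherits(thresholds, "morph_thresholds"), area > 0, diameter > 0)
  e <- diameter / (2 * sqrt(area / pi))
  if (e >= thresholds[["long_cut"]]) "long_tubular"
  else if (e < thresholds[["frag_cut"]]) "fragmented"
  else "short_tubular"
}

#' Quantify a set of outlines into morphology records
#'
#' @param outlines List of [outline_polygon()]s.
#' @param thresholds A [morph_thresholds()].
#' @return Data.frame with `mito_id`, `image_id`, `field_area_um2`,
#'   `area_nm2`, `diameter_nm`, `elongation`, `class`.
#' @export
morph_quantify <- function(outlines, thresholds = morph_thresholds()) {
  rows <- lapply(outlines, function(o) {
    a <- polygon_area(o)
    d <- max_diameter(o)
    data.frame(mito_id = o$mito_id, image_id = o$image_id,
               field_area_um2 = o$field_area_um2, area_nm2 = a,
               diameter_nm = d, elongation = d / (2 * sqrt(a / pi)),
               class = classify_morphology(a, d, thresholds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-image field summaries
#'
#' Counts of whole mitochondria per image field, density per square
#' micrometre and class proportions (summing to 1; flagged undefined for an
#' empty image).
#'
#' @param records Output of [morph_quantify()].
#' @param images Optional image ids to report (default: those present).
#' @param field_area_um2 Named field areas for images with no records.
#' @return Data.frame with one row per image: `image_id`, `count`,
#'   `density_per_um2`, `prop_fragmented`, `prop_short_tubular`,
#'   `prop_long_tubular`, `flag`.
#' @export
field_summary <- function(records, images = NULL, field_area_um2 = NULL) {
  classes <- c("fragmented", "short_tubular", "long_tubular")
  images <- images %||% unique(records$image_id)
  rows <- lapply(images, function(img) {
    sub <- records[records$image_id == img, , drop = FALSE]
    if (!nrow(sub)) {
      fa <- field_area_um2[[img]] %||% NA_real_
      return(data.frame(image_id = img, count = 0L,
                        density_per_um2 = if (is.na(fa)) NA_real_ else 0,
                        prop_fragmented = NA_real_,
                        prop_short_tubular = NA_real_,
                        prop_long_tubular = NA_real_,
                        flag = "undefined: empty image",
                        stringsAsFactors = FALSE))
    }
    fa <- unique(sub$field_area_um2)
    if (length(fa) != 1L)
      stop("field_summary: inconsistent field areas within image '", img, "'")
    pr <- as.numeric(table(factor(sub$class, levels = classes))) / nrow(sub)
    data.frame(image_id = img, count = nrow(sub),
               density_per_um2 = nrow(sub) / fa,
               prop_fragmented = pr[1], prop_short_tubular = pr[2],
               prop_long_tubular = pr[3], flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate synthetic mitochondrial outlines with known classes
#'
#' Draws elliptical outline polygons whose true elongation is sampled inside
#' each class's band (with a safety margin from the cutoffs), applies seeded
#' radial vertex jitter, and returns outlines together with their generating
#' class labels for classifier testing.
#'
#' @param n Number of mitochondria.
#' @param mix Named or ordered numeric weights over
#'   (fragmented, short_tubular, long_tubular), summing to 1.
#' @param mean_area_nm2 Mean area scale (nm^2); areas are lognormal around it.
#' @param jitter Relative radial jitter SD (fraction of local radius).
#' @param n_vertices Polygon resolution.
#' @param field_area_um2 Field area recorded on each outline.
#' @param image_id Image identifier.
#' @param seed Integer seed.
#' @return List with `outlines` (list of [outline_polygon()]) and
#'   `true_class` (character vector).
#' @export
synth_shapes <- function(n, mix = c(fragmented = 1/3, short_tubular = 1/3,
                                    long_tubular = 1/3),
                         mean_area_nm2 = 2e5, jitter = 0.02,
                         n_vertices = 64L, field_area_um2 = 37,
                         image_id = "IMG1", seed = 1L) {
  if (abs(sum(mix) - 1) > 1e-9) stop("synth_shapes: mix must sum to 1")
  set.seed(seed)
  classes <- c("fragmented", "short_tubular", "long_tubular")
  true_class <- sample(classes, n, replace = TRUE, prob = mix)
  # elongation bands kept clear of the default 1.3 / 2.5 cutoffs
  e_range <- list(fragmented = c(1.0, 1.22), short_tubular = c(1.4, 2.3),
                  long_tubular = c(2.7, 4.0))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  outlines <- vector("list", n)
  for (i in seq_len(n)) {
    e <- stats::runif(1, e_range[[true_class[i]]][1],
                      e_range[[true_class[i]]][2])
    area <- stats::rlnorm(1, log(mean_area_nm2), 0.3)
    # ellipse semi-axes: Feret ~ 2a, equal-area circle radius sqrt(ab),
    # so elongation e = sqrt(a/b)
    b <- sqrt(area / pi) / e
    a <- b * e^2
    r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    r <- r * (1 + stats::rnorm(n_vertices, 0, jitter))
    outlines[[i]] <- outline_polygon(
      sprintf("M%04d", i), image_id,
      cbind(r * cos(theta), r * sin(theta)), field_area_um2)
  }
  list(outlines = outlines, true_class = true_class)
}

#' Read outlines from a vertex CSV
#'
#' Columns: `mito_id`, `image_id`, `tracing_index`, `vertex_index`, `x_nm`,
#' `y_nm`, and either a `field_area_um2` column or a named `field_area_um2`
#' argument per image.
#'
#' @param path CSV path.
#' @param field_area_um2 Optional named vector (by image) of field areas.
#' @return List of [outline_polygon()]s.
#' @export
read_outlines <- function(path, field_area_um2 = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mito_id", "image_id", "tracing_index", "vertex_index",
            "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("read_outlines: CSV must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (m in unique(df$mito_id)) {
    sub <- df[df$mito_id == m, ]
    img <- sub$image_id[1]
    fa <- if (!is.null(field_area_um2)) field_area_um2[[img]]
          else sub$field_area_um2[1]
    tracings <- lapply(sort(unique(sub$tracing_index)), function(ti) {
      tr <- sub[sub$tracing_index == ti, ]
      tr <- tr[order(tr$vertex_index), ]
      cbind(tr$x_nm, tr$y_nm)
    })
    out[[length(out) + 1L]] <- outline_polygon(m, img, tracings, fa)
  }
  out
}
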