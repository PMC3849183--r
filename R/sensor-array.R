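#' Construct a mirror-symmetric sensor array
#'
#' Builds a 2-D sensor layout split into a left and a right hemisphere
#' (plus, for the `"ctf-like"` preset with an odd sensor count, midline
#' sensors), together with a distance-threshold neighbour graph and a
#' designated posterior band per hemisphere. The layout emulates the
#' geometry of a whole-head axial-gradiometer system at the level needed
#' for planar-gradient estimation and cluster adjacency: positions are
#' mirror-symmetric across the midline, every non-midline sensor has at
#' least one neighbour, and the lower third of the layout forms the
#' posterior band where simulated attention effects are planted.
#'
#' @param n_sensors Total number of sensors (>= 6). For `"grid"` the count
#'   must be even; `"ctf-like"` accepts odd counts (one midline sensor),
#'   e.g. 273 to match a recorded whole-head system.
#' @param layout_preset `"grid"` (rectangular per-hemisphere grid, used for
#'   small simulations) or `"ctf-like"` (hexagonally packed half-disks).
#' @param neighbor_factor Multiplier on the median nearest-neighbour
#'   distance used as the adjacency threshold.
#'
#' @return A `sensor_array`: a tibble with columns `sensor` (index),
#'   `label`, `x`, `y`, `hemisphere` (`"left"|"right"|"midline"`) and
#'   `posterior` (logical), carrying the logical adjacency matrix in
#'   `attr(, "adjacency")`.
#' @examples
#' sa <- make_sensor_array(30, "grid")
#' table(sa$hemisphere)
#' @export
make_sensor_array <- function(n_sensors,
                              layout_preset = c("grid", "ctf-like"),
                              neighbor_factor = 1.5) {
  layout_preset <- match.arg(layout_preset)
  if (n_sensors < 6) {
    abort("`n_sensors` must be at least 6 to form two posterior bands.")
  }
  if (layout_preset == "grid") {
    if (n_sensors %% 2L != 0L) {
      abort("grid layout requires an even `n_sensors` (no midline column).")
    }
    half <- grid_half(n_sensors %/% 2L)
    pos <- rbind(
      cbind(-half[, 1L], half[, 2L]),  # left: mirrored x
      half
    )
    hemi <- rep(c("left", "right"), each = nrow(half))
  } else {
    n_mid <- n_sensors %% 2L
    k <- (n_sensors - n_mid) %/% 2L
    half <- hex_half(k)
    pos <- rbind(cbind(-half[, 1L], half[, 2L]), half)
    hemi <- rep(c("left", "right"), each = k)
    if (n_mid > 0L) {
      pos <- rbind(pos, cbind(0, 0))
      hemi <- c(hemi, "midline")
    }
  }
  lab_n <- stats::ave(seq_along(hemi), hemi, FUN = seq_along)
  labels <- sprintf("%s%02d", c(left = "L", right = "R", midline = "Z")[hemi], lab_n)
  posterior <- pos[, 2L] <= quantile(pos[, 2L], 1 / 3) & hemi != "midline"
  if (sum(posterior & hemi == "left") < 2L || sum(posterior & hemi == "right") < 2L) {
    abort("`n_sensors` too small: cannot form a posterior band in each hemisphere.")
  }
  d <- as.matrix(stats::dist(pos))
  nn <- apply(d + diag(Inf, nrow(d)), 1L, min)
  adj <- d <= neighbor_factor * median(nn)
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  if (any(deg[hemi != "midline"] == 0L)) {
    abort("layout produced an isolated non-midline sensor; increase `neighbor_factor`.")
  }
  out <- tibble::tibble(
    sensor = seq_len(nrow(pos)),
    label = labels,
    x = pos[, 1L],
    y = pos[, 2L],
    hemisphere = hemi,
    posterior = posterior
  )
  dimnames(adj) <- list(labels, labels)
  attr(out, "adjacency") <- adj
  class(out) <- c("sensor_array", class(out))
  out
}

# near-square grid for one hemisphere, x > 0, unit spacing, gap at midline
grid_half <- function(k) {
  ncol <- ceiling(sqrt(k))
  nrow <- ceiling(k / ncol)
  cells <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
  cells <- cells[order(cells$row, cells$col), , drop = FALSE][seq_len(k), ]
  cbind(x = 0.6 + (cells$col - 1), y = cells$row - (nrow + 1) / 2)
}

# hexagonally packed half-disk: k closest lattice points with x > gap
hex_half <- function(k) {
  r <- ceiling(sqrt(k)) + 3L
  pts <- do.call(rbind, lapply(seq(-r, r), function(j) {
    cbind(x = 0.6 + (seq(0, 2L * r) + (abs(j) %% 2L) / 2), y = j * sqrt(3) / 2)
  }))
  ord <- order(pts[, 1L]^2 + pts[, 2L]^2, pts[, 2L], pts[, 1L])
  pts[ord[seq_len(k)], , drop = FALSE]
}

#' Sensor adjacency as a matrix or neighbour list
#'
#' @param sensors A `sensor_array`.
#' @param as Return form: logical matrix or list of neighbour indices.
#' @return Adjacency matrix or list.
#' @export
sensor_adjacency <- function(sensors, as = c("matrix", "list")) {
  as <- match.arg(as)
  adj <- attr(sensors, "adjacency")
  if (as == "matrix") adj else apply(adj, 1L, which, simplify = FALSE)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array: %d sensors (%d left / %d right / %d midline), %d posterior>\n",
    nrow(x), sum(x$hemisphere == "left"), sum(x$hemisphere == "right"),
    sum(x$hemisphere == "midline"), sum(x$posterior)
  ))
  NextMethod()
}

#' @describeIn make_sensor_array Plot the sensor layout, coloured by
#'   hemisphere with posterior-band sensors filled.
#' @param object,... A `sensor_array` and ignored extra arguments.
#' @method autoplot sensor_array
#' @export
autoplot.sensor_array <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$hemisphere,
                               shape = .data$posterior)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Sensor layout", shape = "posterior band") +
    ggplot2::theme_minimal()
}
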