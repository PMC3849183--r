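#' Alpha modulation index
#'
#' Normalized per-sensor contrast of alpha power between attend-left and
#' attend-right trials:
#' `AM = (P_left - P_right) / (P_left + P_right)`, computed elementwise.
#' Bounded in `[-1, 1]` for nonnegative powers and antisymmetric under
#' swapping the two inputs.
#'
#' @param p_left,p_right Nonnegative power vectors/matrices (mean power
#'   during attend-left and attend-right trials) of equal shape.
#' @return The modulation, same shape as the inputs.
#' @export
alpha_modulation <- function(p_left, p_right) {
  if (!identical(dim(p_left), dim(p_right)) ||
      length(p_left) != length(p_right)) {
    abort("`p_left` and `p_right` must have the same shape.")
  }
  if (any(p_left < 0) || any(p_right < 0)) {
    abort("powers must be nonnegative.")
  }
  tot <- p_left + p_right
  if (any(tot == 0)) {
    abort(sprintf("modulation undefined (both powers zero) at element(s): %s",
                  paste(which(tot == 0), collapse = ", ")))
  }
  (p_left - p_right) / tot
}

#' Per-sensor modulation maps by subject and condition
#'
#' Averages window-averaged alpha power over trials within each subject x
#' condition x hemifield cell and forms the modulation index per sensor.
#'
#' @param summary An `alpha_summary` from [window_average()].
#' @param by Condition columns of the trial metadata defining the cells.
#' @return A tibble with columns `subject`, the `by` columns, `sensor`
#'   (index), `label` and `am`.
#' @export
modulation_maps <- function(summary, by = c("difficulty", "eccentricity")) {
  meta <- summary$trials
  cells <- dplyr::distinct(meta[, c("subject", by), drop = FALSE])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(meta))
    for (cl in c("subject", by)) sel <- sel & meta[[cl]] == cells[[cl]][i]
    pl <- colMeans(summary$power[sel & meta$hemifield == "left", , drop = FALSE])
    pr <- colMeans(summary$power[sel & meta$hemifield == "right", , drop = FALSE])
    dplyr::bind_cols(
      cells[rep(i, ncol(summary$power)), , drop = FALSE],
      tibble::tibble(sensor = seq_along(pl),
                     label = summary$sensors$label,
                     am = alpha_modulation(pl, pr))
    )
  })
  dplyr::bind_rows(out)
}

#' Condition-averaged modulation matrix
#'
#' Averages the per-condition modulation maps (unweighted over
#' conditions) into one map per subject, as a subjects x sensors matrix
#' ready for [define_rois()] / [cluster_permutation_test()].
#'
#' @param maps Output of [modulation_maps()].
#' @return Numeric matrix, subjects (sorted) x sensors.
#' @export
condition_average_maps <- function(maps) {
  avg <- dplyr::summarise(
    dplyr::group_by(maps, .data$subject, .data$sensor),
    am = mean(.data$am), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(avg, names_from = "sensor", values_from = "am")
  wide <- dplyr::arrange(wide, .data$subject)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$subject
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' Alpha lateralization index
#'
#' Difference of the mean modulation over the left-hemisphere ROI and the
#' mean modulation over the right-hemisphere ROI:
#' `AL = mean(AM[left ROI]) - mean(AM[right ROI])`. Flips sign when the
#' two ROIs are exchanged.
#'
#' @param am Modulation per sensor: a vector, or a matrix with sensors in
#'   columns (one AL per row).
#' @param rois A `roi_pair`; both ROIs must be nonempty.
#' @return Scalar (or per-row vector) lateralization.
#' @export
alpha_lateralization <- function(am, rois) {
  if (!length(rois$left) || !length(rois$right)) {
    abort("both ROIs must be nonempty to form a lateralization index.")
  }
  if (is.matrix(am)) {
    rowMeans(am[, rois$left, drop = FALSE]) -
      rowMeans(am[, rois$right, drop = FALSE])
  } else {
    mean(am[rois$left]) - mean(am[rois$right])
  }
}

#' Per-subject, per-condition lateralization table
#'
#' @param maps Output of [modulation_maps()].
#' @param rois A `roi_pair`.
#' @param by Condition columns.
#' @return A tibble with `subject`, the `by` columns and `al`.
#' @export
lateralization_table <- function(maps, rois, by = c("difficulty", "eccentricity")) {
  grp <- dplyr::group_by(maps, dplyr::across(dplyr::all_of(c("subject", by))))
  dplyr::summarise(
    grp,
    al = mean(.data$am[.data$sensor %in% rois$left]) -
      mean(.data$am[.data$sensor %in% rois$right]),
    .groups = "drop"
  )
}

#' @describeIn modulation_maps Plot a modulation map on the sensor
#'   layout.
#' @param sensors A `sensor_array`.
#' @param am Modulation vector (one value per sensor).
#' @param rois Optional `roi_pair`; member sensors are outlined.
#' @export
plot_modulation_map <- function(sensors, am, rois = NULL) {
  df <- tibble::as_tibble(sensors)
  df$am <- am
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$am)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Alpha modulation", colour = "AM") +
    ggplot2::theme_minimal()
  if (!is.null(rois)) {
    sel <- df[c(rois$left, rois$right), , drop = FALSE]
    p <- p + ggplot2::geom_point(data = sel, shape = 21, size = 6,
                                 colour = "black", fill = NA)
  }
  p
}
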