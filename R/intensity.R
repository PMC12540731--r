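#' Background-corrected ROI intensity
#'
#' Subtracts the cytoplasmic background from the ROI mean signal. When
#' the measurement is an integrated sum over a z projection, it is first
#' divided by the number of z planes so that signal and background are on
#' the same per-plane scale. Corrected values are clamped at zero (with a
#' flag) so that downstream ratios stay interpretable.
#'
#' @param mean_signal ROI signal, a.u. (vectorized). Mean per plane, or
#'   the integrated sum when `integrated = TRUE`.
#' @param background_mean Cytoplasmic background per plane, a.u.
#' @param n_z_planes Number of z planes in the projection (used only when
#'   `integrated = TRUE`).
#' @param integrated Is `mean_signal` an integrated sum over the
#'   projection?
#' @return A tibble with columns `corrected` (a.u.) and `clipped`
#'   (logical: the background exceeded the signal).
#' @examples
#' corrected_intensity(150, 30)                            # 120
#' corrected_intensity(1200, 30, n_z_planes = 6,
#'                     integrated = TRUE)                  # 170
#' @export
corrected_intensity <- function(mean_signal, background_mean,
                                n_z_planes = 1L, integrated = FALSE) {
  if (any(mean_signal < 0, na.rm = TRUE) ||
      any(background_mean < 0, na.rm = TRUE)) {
    stop("signal and background intensities must be non-negative",
         call. = FALSE)
  }
  if (any(n_z_planes < 1, na.rm = TRUE)) {
    stop("n_z_planes must be >= 1", call. = FALSE)
  }
  per_plane <- if (integrated) mean_signal / n_z_planes else mean_signal
  raw <- per_plane - background_mean
  tibble::tibble(corrected = pmax(raw, 0), clipped = raw < 0)
}

#' Normalize a corrected intensity to a reference channel
#'
#' Divides the background-corrected signal by the background-corrected
#' reference (CENP-A for kinetochore ROIs), removing kinetochore-size and
#' depth effects.
#'
#' @param corrected Corrected signal, a.u. (vectorized).
#' @param reference_corrected Corrected reference signal, a.u.; must be
#'   strictly positive.
#' @param roi_id Optional ROI labels used in error messages.
#' @return Numeric ratio vector.
#' @export
normalize_to_reference <- function(corrected, reference_corrected,
                                   roi_id = NULL) {
  bad <- !is.na(reference_corrected) & reference_corrected <= 0
  if (any(bad)) {
    lab <- if (is.null(roi_id)) paste(which(bad), collapse = ", ")
    else paste(roi_id[bad], collapse = ", ")
    stop("undefined ratio: non-positive reference intensity for ROI(s) ",
         lab, call. = FALSE)
  }
  corrected / reference_corrected
}

#' Exclude kinetochore samples inside the pole signal
#'
#' Phospho-antibodies against outer-kinetochore proteins label the
#' spindle poles non-specifically, so kinetochore-pair samples within the
#' circular pole signal (~1 µm from the centrosome) are discarded. The
#' boundary is excluded: a sample exactly at the radius is removed
#' ("outside" is read strictly). Pole samples are never filtered. The
#' filter is idempotent.
#'
#' @param samples Intensity sample tibble (see [simulate_intensities()]
#'   for the schema).
#' @param cfg An [analysis_config()]; `pole_exclusion_radius` is the
#'   cut-off in µm.
#' @return The filtered tibble, with attribute `n_removed`.
#' @export
pole_exclusion_filter <- function(samples, cfg = analysis_config()) {
  drop <- samples$roi_kind == "kinetochore_pair" &
    !is.na(samples$dist_to_nearest_pole) &
    samples$dist_to_nearest_pole <= cfg$pole_exclusion_radius
  out <- samples[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Ratio of pole intensity at the centriolar versus acentriolar pole
#'
#' For a cell with one centriolar and one acentriolar pole, the ratio of
#' background-corrected pole signals, centriolar over acentriolar. For a
#' cell whose poles are of the same class (1:1 or 2:2 spindles) the
#' maximum-over-minimum ratio is returned with `symmetric_pair = TRUE`,
#' supporting the maximum-difference-between-poles readout.
#'
#' @param samples Intensity samples of one cell (must contain exactly two
#'   `pole` rows).
#' @return A tibble with one row: `cell_id`, `ratio`, `symmetric_pair`.
#' @export
pole_ratio <- function(samples) {
  poles <- samples[samples$roi_kind == "pole", , drop = FALSE]
  if (nrow(poles) != 2) {
    stop("pole_ratio needs exactly 2 pole samples per cell, got ",
         nrow(poles), call. = FALSE)
  }
  corr <- corrected_intensity(poles$mean_signal, poles$background_mean)
  cls <- poles$location_class
  if (setequal(cls, c("pole_centriolar", "pole_acentriolar"))) {
    num <- corr$corrected[cls == "pole_centriolar"]
    den <- corr$corrected[cls == "pole_acentriolar"]
    sym <- FALSE
  } else if (length(unique(cls)) == 1) {
    num <- max(corr$corrected)
    den <- min(corr$corrected)
    sym <- TRUE
  } else {
    stop("unrecognized pole class combination: ",
         paste(cls, collapse = ", "), call. = FALSE)
  }
  if (den <= 0) {
    stop("pole_ratio undefined: denominator pole has zero corrected ",
         "intensity in cell ", poles$cell_id[1], call. = FALSE)
  }
  tibble::tibble(cell_id = poles$cell_id[1], ratio = num / den,
                 symmetric_pair = sym)
}

#' Per-cell polar versus aligned normalized kinetochore intensity ratio
#'
#' Mean reference-normalized kinetochore intensity on polar kinetochores
#' divided by the same mean on aligned kinetochores, one ratio per cell.
#' Cells missing either class are skipped (reported in the
#' `skipped_cells` attribute). Samples inside the pole exclusion radius
#' should be filtered out beforehand via [pole_exclusion_filter()].
#'
#' @param samples Intensity sample tibble, possibly spanning many cells.
#' @return A tibble with columns `cell_id`, `n_polar`, `n_aligned`,
#'   `ratio`; attribute `skipped_cells` lists cells missing a class.
#' @export
polar_vs_aligned_ratio <- function(samples) {
  kc <- samples[samples$roi_kind == "kinetochore_pair", , drop = FALSE]
  corr <- corrected_intensity(kc$mean_signal, kc$background_mean)
  kc$norm <- normalize_to_reference(corr$corrected,
                                    kc$reference_mean, kc$roi_id)
  skipped <- character(0)
  rows <- lapply(split(kc, kc$cell_id), function(d) {
    pol <- d$norm[d$location_class == "polar"]
    ali <- d$norm[d$location_class == "aligned"]
    if (length(pol) == 0 || length(ali) == 0) return(NULL)
    tibble::tibble(cell_id = d$cell_id[1],
                   n_polar = length(pol), n_aligned = length(ali),
                   ratio = mean(pol) / mean(ali))
  })
  keep <- !vapply(rows, is.null, logical(1))
  skipped <- names(rows)[!keep]
  out <- dplyr::bind_rows(rows[keep])
  attr(out, "skipped_cells") <- skipped
  out
}

#' Phospho-intensity gradient with distance from the pole
#'
#' OLS regression of the reference-normalized kinetochore intensity on
#' the distance of the pair from its nearest pole, quantifying the
#' spatial fall-off of pole-driven phosphorylation. Apply
#' [pole_exclusion_filter()] first.
#'
#' @param samples Intensity sample tibble (kinetochore-pair rows are
#'   used; at least 3 required).
#' @return An [ols_slope_test()] tibble.
#' @export
gradient_regression <- function(samples) {
  kc <- samples[samples$roi_kind == "kinetochore_pair", , drop = FALSE]
  if (nrow(kc) < 3) {
    stop("gradient_regression needs at least 3 kinetochore samples",
         call. = FALSE)
  }
  corr <- corrected_intensity(kc$mean_signal, kc$background_mean)
  norm <- normalize_to_reference(corr$corrected, kc$reference_mean,
                                 kc$roi_id)
  ols_slope_test(kc$dist_to_nearest_pole, norm)
}
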