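#' Tissue total water content constants
#'
#' Literature constants used to convert water fractions of tissue *water*
#' into absolute fractions of tissue *volume*: TWC = 83% in grey matter and
#' 70% in white matter.
#'
#' @param gm,wm total water content per tissue, in (0,1]
#' @return list with `gm` and `wm`
#' @export
twc_constants <- function(gm = 0.83, wm = 0.70) {
  if (any(c(gm, wm) <= 0) || any(c(gm, wm) > 1))
    stop_invalid("TWC values must lie in (0,1]")
  list(gm = gm, wm = wm)
}

#' Calibrate a water-fraction map to an absolute fluid fraction
#'
#' Multiplies the fraction map by the tissue total water content: pCSF =
#' pCSFF * TWC, and the free-water map is converted the same way. GM voxels
#' are scaled by `twc$gm`, WM voxels by `twc$wm`; voxels outside both masks
#' are set to zero. The mapping is order-preserving within each tissue.
#'
#' @param frac_map 3D array of fractions in [0,1]
#' @param gm_mask,wm_mask disjoint tissue masks
#' @param twc [twc_constants()]
#' @return calibrated 3D array
#' @export
calibrate_fraction_map <- function(frac_map, gm_mask, wm_mask,
                                   twc = twc_constants()) {
  check_same_grid(frac_map, gm_mask, wm_mask, what = "map/masks")
  if (any(gm_mask & wm_mask)) stop_invalid("GM and WM masks overlap")
  rng <- range(frac_map[gm_mask | wm_mask], 0)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop_invalid("fraction map must lie in [0,1]")
  out <- array(0, dim(frac_map))
  out[gm_mask] <- frac_map[gm_mask] * twc$gm
  out[wm_mask] <- frac_map[wm_mask] * twc$wm
  out
}

#' ROI mean of a calibrated map, in percent
#'
#' Arithmetic mean over `roi_mask` minus `exclude_mask` (e.g. the WMH mask is
#' excluded from WM ROIs), reported in percent.
#'
#' @param map 3D array of fractions in [0,1]
#' @param roi_mask logical ROI
#' @param exclude_mask logical exclusion mask, or `NULL`
#' @return scalar, percent
#' @export
roi_mean <- function(map, roi_mask, exclude_mask = NULL) {
  eff <- roi_mask
  if (!is.null(exclude_mask)) eff <- eff & !exclude_mask
  if (!any(eff)) stop_invalid("effective ROI is empty")
  100 * mean(map[eff])
}

#' Standardized uptake value ratio
#'
#' Mean PET uptake in the target mask divided by the mean in the reference
#' mask (cerebellar cortex). Invariant to any positive global rescaling of
#' the PET volume.
#'
#' @param pet 3D uptake volume
#' @param target_mask,ref_mask nonempty logical masks
#' @return SUVR scalar
#' @export
compute_suvr <- function(pet, target_mask, ref_mask) {
  if (!any(target_mask) || !any(ref_mask))
    stop_invalid("target and reference masks must be nonempty")
  ref <- mean(pet[ref_mask])
  if (ref == 0) stop_invalid("reference-region mean uptake is zero")
  mean(pet[target_mask]) / ref
}

#' Assemble the per-subject biomarker table
#'
#' One row per subject with covariates and measured biomarkers (WM/GM/ADmask
#' pCSF, WM FW and PVS/WMV in percent; SUVR as a ratio), ordered by id.
#' Subjects with missing stage outputs are dropped with a warning.
#'
#' @param measurements list of per-subject named lists, each carrying `id`,
#'   `age`, `sex`, `dx`, `apoe4` plus the biomarker values
#' @return data.frame of class `glymap_biomarker_table`
#' @export
build_subject_table <- function(measurements) {
  cols <- c("id", "age", "sex", "dx", "apoe4", "wm_pcsf", "gm_pcsf",
            "admask_pcsf", "wm_fw", "pvs_wmv", "suvr")
  rows <- list()
  for (m in measurements) {
    missing <- setdiff(cols, names(m))
    if (length(missing)) {
      warning("subject ", m$id %||% "<unknown>", ": missing ",
              paste(missing, collapse = ", "), "; row dropped")
      next
    }
    rows[[length(rows) + 1L]] <- as.data.frame(m[cols], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    tab <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
  } else {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("glymap_biomarker_table", "data.frame")
  tab
}
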