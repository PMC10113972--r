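#' Mask volume in millilitres
#'
#' @param mask a [mask_volume()].
#' @return `count(TRUE) * dz*dy*dx / 1000` in mL.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$voxels) * voxel_volume_ml(mask)
}

#' Severity class from the contusion ratio
#'
#' Moderate when the contusion occupies at most 20% of the total lung
#' volume, severe above 20%. The boundary value 20% itself is moderate.
#'
#' @param ratio contusion ratio in percent, in \[0, 100\].
#' @return `"moderate"` or `"severe"`.
#' @export
classify_severity <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 100))
    cv_stop("cv_domain_error", "contusion ratio must be within [0, 100] percent")
  ifelse(ratio <= 20, "moderate", "severe")
}

#' Contusion ratio and volume report
#'
#' Computes per-class volumes and the contusion-to-total-lung ratio.
#' Pneumothorax bookkeeping is contested: the default counts pleural air
#' with the normal lung (collapsed lung re-expands after thoracostomy), so
#' it is excluded from the contusion volume but remains inside the total;
#' `ptx_counts_as = "contusion"` adds it to the contusion volume instead.
#' Both assignments conserve volume: the buckets always sum to the total.
#'
#' @param part a [lung_partition()].
#' @param ptx_counts_as `"normal"` (default) or `"contusion"`.
#' @return A `volume_report`: volumes `v_total`, `v_normal`, `v_contusion`,
#'   `v_ptx` (mL), `contusion_ratio` and `normal_percent` (%), `severity`,
#'   and the assignment used.
#' @export
contusion_ratio <- function(part, ptx_counts_as = c("normal", "contusion")) {
  stopifnot(inherits(part, "lung_partition"))
  ptx_counts_as <- match.arg(ptx_counts_as)
  v_total <- mask_volume_ml(part$total)
  if (v_total <= 0)
    cv_stop("cv_domain_error", "total lung volume is zero; ratio undefined")
  v_normal <- mask_volume_ml(part$normal)
  v_cont <- mask_volume_ml(part$contusion)
  v_ptx <- mask_volume_ml(part$pneumothorax)
  v_cont_eff <- if (ptx_counts_as == "contusion") v_cont + v_ptx else v_cont
  ratio <- 100 * v_cont_eff / v_total
  structure(list(
    v_total = v_total, v_normal = v_normal, v_contusion = v_cont,
    v_ptx = v_ptx,
    ptx_counts_as = ptx_counts_as,
    contusion_ratio = ratio,
    normal_percent = 100 - ratio,
    severity = classify_severity(ratio)
  ), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("volume_report: total %.1f mL, contusion %.1f mL, pneumothorax %.1f mL (counted as %s)\n",
              x$v_total, x$v_contusion, x$v_ptx, x$ptx_counts_as))
  cat(sprintf("  contusion ratio %.2f%% -> %s (cutoff: >20%% is severe)\n",
              x$contusion_ratio, x$severity))
  invisible(x)
}

#' Serialize a volume report
#'
#' JSON for single reports; `append_volume_report_csv()` adds one row per
#' CT to a running CSV.
#'
#' @param report a `volume_report`.
#' @param path destination file.
#' @param id row identifier for the CSV form.
#' @export
write_volume_report <- function(report, path) {
  stopifnot(inherits(report, "volume_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume_report
#' @export
append_volume_report_csv <- function(report, path, id = NA_character_) {
  stopifnot(inherits(report, "volume_report"))
  row <- data.frame(id = id, as.data.frame(unclass(report)),
                    stringsAsFactors = FALSE)
  write.table(row, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path),
              qmethod = "double")
  invisible(path)
}

#' Arterial blood gas container
#'
#' FiO2 is an inspired-oxygen fraction in (0.21, 1\]; values above 1.5 are
#' taken to be percentages and divided by 100 (with a message), since
#' clinical records mix both conventions.
#'
#' @param pao2 arterial oxygen partial pressure, mmHg, > 0.
#' @param fio2 inspired oxygen fraction (or percent, auto-detected).
#' @return A `blood_gas` with `pao2`, `fio2` and `pf_ratio = pao2 / fio2`.
#' @export
blood_gas <- function(pao2, fio2) {
  if (!is.finite(pao2) || pao2 <= 0)
    cv_stop("cv_domain_error", "pao2 must be a positive pressure in mmHg")
  if (is.finite(fio2) && fio2 > 1.5) {
    message(sprintf("fio2 = %.1f interpreted as a percentage; using %.2f", fio2, fio2 / 100))
    fio2 <- fio2 / 100
  }
  if (!is.finite(fio2) || fio2 < 0.21 || fio2 > 1.0)
    cv_stop("cv_domain_error", "fio2 must lie in [0.21, 1.0] as a fraction")
  structure(list(pao2 = pao2, fio2 = fio2, pf_ratio = pao2 / fio2),
            class = "blood_gas")
}

#' ARDS flag
#'
#' True when the P/F ratio is at most 200 mmHg, bilateral diffuse
#' infiltration is present, and congestive heart failure is absent.
#'
#' @param bg a [blood_gas()].
#' @param bilateral_infiltration logical, bilateral diffuse infiltration on
#'   chest radiography.
#' @param chf logical, evidence of congestive heart failure.
#' @return logical.
#' @export
ards_flag <- function(bg, bilateral_infiltration, chf) {
  stopifnot(inherits(bg, "blood_gas"))
  isTRUE(bg$pf_ratio <= 200) && isTRUE(bilateral_infiltration) && !isTRUE(chf)
}
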