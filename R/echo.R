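#' Fractional shortening from M-mode internal diameters
#'
#' `FS = (LVIDd - LVIDs) / LVIDd * 100%`.
#'
#' @param lvid_d,lvid_s Left-ventricular internal diameter at end-diastole /
#'   end-systole (mm). Vectorized.
#' @return Fractional shortening in percent.
#' @examples
#' fractional_shortening(3.0, 1.9) # 36.667
#' @export
fractional_shortening <- function(lvid_d, lvid_s) {
  if (any(!is.finite(lvid_d)) || any(lvid_d <= 0)) {
    abort_param("lvid_d", "must be > 0")
  }
  if (any(lvid_d < lvid_s, na.rm = TRUE)) {
    warn("lvid_d < lvid_s for some rows: negative fractional shortening")
  }
  (lvid_d - lvid_s) / lvid_d * 100
}

#' Teichholz single-diameter ventricular volume
#'
#' `V = 7 / (2.4 + LVID) * LVID^3`, with the diameter in mm and the volume
#' in uL (the cubic-formula convention used with murine M-mode
#' measurements).
#'
#' @param lvid Internal diameter, mm. Vectorized.
#' @return Volume in uL.
#' @examples
#' teichholz_volume(3.0) # 35
#' @export
teichholz_volume <- function(lvid) {
  if (any(!is.finite(lvid)) || any(lvid < 0)) {
    abort_param("lvid", "must be >= 0")
  }
  7 / (2.4 + lvid) * lvid^3
}

#' Stroke volume and ejection fraction
#'
#' `SV = EDV - ESV`; `EF = SV / EDV * 100%`.
#'
#' @param edv,esv End-diastolic / end-systolic volume, uL. Vectorized.
#' @return Tibble with columns `sv_uL`, `ef_pct`.
#' @examples
#' stroke_volume_ef(35, 11.165)
#' @export
stroke_volume_ef <- function(edv, esv) {
  if (any(!is.finite(edv)) || any(edv <= 0)) {
    abort_param("edv", "must be > 0")
  }
  if (any(esv > edv, na.rm = TRUE)) {
    warn("esv > edv for some rows: negative stroke volume passed through")
  }
  sv <- edv - esv
  tibble::tibble(sv_uL = sv, ef_pct = sv / edv * 100)
}

#' Derived echocardiographic parameters for a measurement table
#'
#' Adds FS, Teichholz ESV/EDV, SV, and EF columns to a per-animal table of
#' M-mode measurements. Group summaries of the derived values are means of
#' per-animal values (not derived values of group-mean diameters).
#'
#' @param measurements Data frame with columns `lvid_d` and `lvid_s` (mm;
#'   `_mm` suffixes also recognized); other columns pass through.
#' @return The input tibble with `fs_pct`, `edv_uL`, `esv_uL`, `sv_uL`,
#'   `ef_pct` appended.
#' @examples
#' echo_derive(tibble::tibble(animal_id = "m1", lvid_d = 3.0, lvid_s = 1.9))
#' @export
echo_derive <- function(measurements) {
  df <- tibble::as_tibble(measurements)
  pick <- function(nm) {
    hit <- intersect(c(nm, paste0(nm, "_mm")), names(df))
    if (!length(hit)) {
      abort(sprintf("missing column `%s` in measurement table", nm),
        class = "cardiophen_format_error"
      )
    }
    df[[hit[1]]]
  }
  lvid_d <- pick("lvid_d")
  lvid_s <- pick("lvid_s")
  edv <- teichholz_volume(lvid_d)
  esv <- teichholz_volume(lvid_s)
  dplyr::bind_cols(
    df,
    tibble::tibble(
      fs_pct = fractional_shortening(lvid_d, lvid_s),
      edv_uL = edv, esv_uL = esv
    ),
    stroke_volume_ef(edv, esv)
  )
}
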