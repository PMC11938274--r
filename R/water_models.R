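# Registry of the four rigid explicit water models the scale is calibrated
# against. Values are stored at the precision they are published at and are
# never re-derived; the registry is the single source for counting geometry
# and for emitted MD configuration.

.water_model_registry <- local({
  reg <- tibble::tribble(
    ~model_id,  ~q_H,    ~q_O,   ~q_V,     ~n_virtual_sites, ~d_OH,   ~d_OV,  ~theta_HOH, ~theta_VOV, ~sigma_O, ~epsilon_O,
    "TIP3P",    0.417,  -0.834,  NA_real_, 0L,               0.09572, NA_real_, 104.52,   NA_real_,   0.315057, 0.63639,
    "TIP4P",    0.52,    0,     -1.040,    1L,               0.09572, 0.015,    104.52,   NA_real_,   0.315365, 0.64852,
    "TIP4P-Ew", 0.52422, 0,     -1.04844,  1L,               0.09572, 0.0125,   104.52,   NA_real_,   0.315365, 0.64852,
    "TIP5P",    0.241,   0,     -0.241,    2L,               0.09572, 0.070,    104.52,   109.47,     0.312000, 0.66944
  )
  reg$note <- c(
    "CHARMM-modified TIP3P variant as used with CHARMM36m proteins",
    "Jorgensen four-site model; negative charge on the M virtual site",
    "TIP4P reparameterized for Ewald electrostatics",
    "Five-site model; negative charge on two lone-pair virtual sites"
  )
  reg
})

#' Table of registered explicit water models
#'
#' Returns the full parameter registry for the four supported rigid water
#' models: TIP3P (the CHARMM-modified variant), TIP4P, TIP4P-Ew and TIP5P.
#' Charges are in elementary charge units (e), distances in nm, angles in
#' degrees, and Lennard-Jones parameters in nm (`sigma_O`) and kJ/mol
#' (`epsilon_O`). Virtual-site columns are `NA` where a model has no such
#' site (TIP3P has none; TIP5P has two lone pairs).
#'
#' @return A tibble with one row per model and columns `model_id`, `q_H`,
#'   `q_O`, `q_V`, `n_virtual_sites`, `d_OH`, `d_OV`, `theta_HOH`,
#'   `theta_VOV`, `sigma_O`, `epsilon_O`, `note`.
#' @export
#' @examples
#' water_models()
water_models <- function() {
  .water_model_registry
}

# Accepts case-insensitive ids and the common hyphenless spellings
# ("tip4pew" -> "TIP4P-Ew").
normalize_water_model_id <- function(model_id) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  key <- toupper(gsub("[-_ ]", "", model_id))
  lut <- c(TIP3P = "TIP3P", TIP4P = "TIP4P", TIP4PEW = "TIP4P-Ew", TIP5P = "TIP5P")
  if (!key %in% names(lut)) {
    stop(
      "Unknown water model '", model_id, "'. Registered models: ",
      paste(.water_model_registry$model_id, collapse = ", "),
      call. = FALSE
    )
  }
  unname(lut[[key]])
}

#' Retrieve one water model's parameter set
#'
#' @param model_id One of `"TIP3P"`, `"TIP4P"`, `"TIP4P-Ew"`, `"TIP5P"`
#'   (case-insensitive; `"tip4pew"` is accepted for TIP4P-Ew).
#' @return A one-row tibble with the columns of [water_models()].
#' @export
#' @examples
#' get_water_model("TIP5P")$q_H        # 0.241 e
#' get_water_model("tip4pew")$d_OV     # 0.0125 nm
get_water_model <- function(model_id) {
  id <- normalize_water_model_id(model_id)
  dplyr::filter(.water_model_registry, .data$model_id == id)
}

#' Net molecular charge of a water model
#'
#' Computes `2 * q_H + q_O + n_virtual_sites * q_V` in elementary charge
#' units. Every registered model is electrically neutral to within 1e-10 e;
#' this is exposed as a sanity check and for user-supplied parameter sets.
#'
#' @param params A one-row parameter tibble as returned by
#'   [get_water_model()], or a named list with fields `q_H`, `q_O`,
#'   `n_virtual_sites` and (if `n_virtual_sites > 0`) `q_V`.
#' @return Net charge in e.
#' @export
#' @examples
#' net_charge(get_water_model("TIP3P"))  # 0
net_charge <- function(params) {
  qv <- if (params$n_virtual_sites > 0L) params$q_V else 0
  2 * params$q_H + params$q_O + params$n_virtual_sites * qv
}

#' Export a water model as a plain-text key-value block
#'
#' Formats one model's parameters as `key = value` lines suitable for
#' inclusion in emitted MD configuration files or run manifests. `NA`
#' fields (absent sites) are omitted.
#'
#' @inheritParams get_water_model
#' @return A character vector of lines.
#' @export
water_model_block <- function(model_id) {
  p <- get_water_model(model_id)
  fields <- c(
    "model_id", "q_H", "q_O", "q_V", "n_virtual_sites",
    "d_OH", "d_OV", "theta_HOH", "theta_VOV", "sigma_O", "epsilon_O"
  )
  vals <- lapply(fields, function(f) p[[f]])
  keep <- !vapply(vals, function(v) is.na(v), logical(1))
  paste0(
    fields[keep], " = ",
    vapply(vals[keep], function(v) format(v, trim = TRUE), character(1))
  )
}
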