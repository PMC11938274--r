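# The PARCH statistic. A residue's water-count series w_i(t), recorded
# while the solvent is heated, is turned into a hydropathy value in four
# steps: (1) a monotone envelope (running minimum) encodes irreversible
# water loss, (2) a non-centered autocorrelation of the envelope measures
# retention, (3) its mean over all lags gives one number per residue,
# (4) normalization against the best-retaining reference residue and a
# factor of 10 put the value on the 0-10 scale.
#
# Each mathematical step lives in exactly one function so an alternative
# form (mean-subtracted autocorrelation, a shorter lag window) is a
# one-line swap.

#' Monotone envelope of a water-count series
#'
#' Imposes the monotonicity condition on a raw count series: the envelope
#' is the running minimum, `eta(t_0) = w(t_0)`,
#' `eta(t_k) = min(eta(t_{k-1}), w(t_k))`. Transient re-adsorption blips
#' are thereby discarded; only irreversible water loss remains.
#'
#' @param w Numeric vector of nonnegative counts in time order.
#' @return Numeric vector of the same length, non-increasing.
#' @export
#' @examples
#' monotone_envelope(c(5, 6, 4, 5, 3)) # 5 5 4 4 3
monotone_envelope <- function(w) {
  if (length(w) == 0L) stop("Empty series.", call. = FALSE)
  if (anyNA(w)) stop("Series contains NA counts.", call. = FALSE)
  cummin(w)
}

#' Non-centered autocorrelation of a monotone envelope
#'
#' For an envelope of length `T`, returns
#' `C(tau) = [(1/(T-tau)) * sum_t eta(t) eta(t+tau)] /
#'           [(1/T) * sum_t eta(t)^2]`
#' for `tau = 0..tau_max`. The normalization is non-centered (no mean
#' subtraction): a constant series has `C == 1` (perfect retention), and
#' an all-zero series is defined as `C == 0` with a `degenerate`
#' attribute set (a residue with no access to water). Because the
#' numerator is normalized by the lag count `T - tau` while the
#' denominator uses `T`, individual lags can exceed 1 by up to
#' `T / (T - tau)`; boundedness of the final value is enforced by the
#' clipping in [parch_value()].
#'
#' @param eta Nonnegative, non-increasing numeric vector (the envelope).
#' @param tau_max Largest lag; default all lags, `length(eta) - 1`.
#' @return Numeric vector `C(0..tau_max)`, attribute `degenerate` TRUE for
#'   an all-zero input.
#' @export
#' @examples
#' autocorrelation(c(2, 1)) # 1.0 0.8
autocorrelation <- function(eta, tau_max = length(eta) - 1L) {
  n <- length(eta)
  if (n == 0L) stop("Empty series.", call. = FALSE)
  if (any(eta < 0)) stop("Envelope must be nonnegative.", call. = FALSE)
  if (any(diff(eta) > 0)) {
    stop("Envelope must be non-increasing; apply monotone_envelope() first.",
      call. = FALSE
    )
  }
  tau_max <- min(as.integer(tau_max), n - 1L)
  if (sum(eta^2) == 0) {
    out <- rep(0, tau_max + 1L)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # lagged products via FFT: r[tau] = sum_t eta(t) eta(t + tau)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(eta, rep(0, m - n)))
  r <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(tau_max + 1L)] / m
  num <- r / (n - 0:tau_max)
  denom <- r[1] / n
  out <- pmax(num / denom, 0) # clamp FFT roundoff below zero
  out[1] <- 1
  attr(out, "degenerate") <- FALSE
  out
}

#' Time-averaged autocorrelation
#'
#' Arithmetic mean of `C(tau)` over the computed lags; one retention
#' number per residue, in `[0, 1]`.
#'
#' @param cvals Numeric vector from [autocorrelation()].
#' @return Scalar mean.
#' @export
time_averaged_autocorrelation <- function(cvals) {
  if (length(cvals) == 0L) stop("Empty autocorrelation curve.", call. = FALSE)
  mean(cvals)
}

# envelope -> autocorrelation -> mean, for one raw count series
cbar_of_series <- function(w, tau_max = NULL) {
  eta <- monotone_envelope(w)
  if (is.null(tau_max)) tau_max <- length(eta) - 1L
  time_averaged_autocorrelation(autocorrelation(eta, tau_max))
}

#' Select the reference residue
#'
#' The reference is the candidate with the highest time-averaged
#' autocorrelation (in calibration against the 20 zwitterionic amino
#' acids this is lysine for all four water models). Ties break by
#' lexicographic three-letter code.
#'
#' @param cbars Named numeric vector: candidate residue name -> `C-bar`.
#' @return The winning residue name.
#' @export
select_reference <- function(cbars) {
  if (length(cbars) == 0L) stop("No reference candidates.", call. = FALSE)
  if (is.null(names(cbars)) || any(names(cbars) == "")) {
    stop("Candidates must be named by residue.", call. = FALSE)
  }
  ord <- order(-cbars, names(cbars), method = "radix")
  names(cbars)[ord[1]]
}

#' Standardize a retention value to the PARCH 0-10 scale
#'
#' `PV = 10 * cbar / cbar_ref`, clipped to `[0, 10]`. The reference
#' residue scores exactly 10 by construction; a residue with `cbar = 0`
#' (no water retained, or never hydrated) scores 0. Values above the
#' reference are clipped to 10; the unclipped value is kept in the
#' `"unclipped"` attribute for diagnostics.
#'
#' @param cbar Residue's time-averaged autocorrelation, `>= 0`.
#' @param cbar_ref Reference's value, `> 0`.
#' @return PARCH value in `[0, 10]`.
#' @export
parch_value <- function(cbar, cbar_ref) {
  if (length(cbar_ref) != 1L || is.na(cbar_ref) || cbar_ref <= 0) {
    stop("Invalid reference: cbar_ref must be a single positive value.",
      call. = FALSE
    )
  }
  if (any(cbar < 0)) stop("cbar must be nonnegative.", call. = FALSE)
  raw <- 10 * cbar / cbar_ref
  out <- pmin(pmax(raw, 0), 10)
  if (any(raw > 10)) attr(out, "unclipped") <- raw
  out
}

residue_key_cols <- function(df) {
  intersect(c("chain", "resid", "resname"), names(df))
}

validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  keys <- residue_key_cols(counts)
  if (length(keys) == 0L) {
    stop("Counts need at least one residue key column ",
      "('chain', 'resid', 'resname').",
      call. = FALSE
    )
  }
  for (col in c("time_ps", "count")) {
    if (!col %in% names(counts)) {
      stop("Counts are missing the '", col, "' column.", call. = FALSE)
    }
  }
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  counts
}

# cbar per (residue, replicate)
cbar_table <- function(counts, tau_max = NULL) {
  counts <- validate_counts(counts)
  keys <- residue_key_cols(counts)
  counts |>
    dplyr::arrange(.data$time_ps) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "replicate")))) |>
    dplyr::summarise(
      cbar = cbar_of_series(.data$count, tau_max = tau_max),
      .groups = "drop"
    )
}

resolve_reference <- function(cb, reference, keys) {
  if (is.numeric(reference)) {
    if (length(reference) != 1L || reference <= 0) {
      stop("A numeric reference must be a single positive cbar value.",
        call. = FALSE
      )
    }
    return(list(
      table = dplyr::distinct(cb, .data$replicate) |>
        dplyr::mutate(cbar_ref = reference),
      resname = NA_character_, how = "fixed cbar"
    ))
  }
  if (is.data.frame(reference)) {
    ref_cb <- cbar_table(reference)
    tab <- ref_cb |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(cbar_ref = max(.data$cbar), .groups = "drop")
    if (!all(unique(cb$replicate) %in% tab$replicate)) {
      tab <- tibble::tibble(
        replicate = unique(cb$replicate),
        cbar_ref = mean(ref_cb$cbar)
      )
    }
    return(list(table = tab, resname = NA_character_, how = "reference series"))
  }
  # character resname, or NULL -> select by maximal replicate-mean cbar
  if (!"resname" %in% keys) {
    stop("Selecting a reference within the cohort needs a 'resname' column; ",
      "supply a numeric reference instead.",
      call. = FALSE
    )
  }
  by_name <- cb |>
    dplyr::group_by(.data$resname) |>
    dplyr::summarise(cbar = mean(.data$cbar), .groups = "drop")
  ref_name <- if (is.null(reference)) {
    select_reference(stats::setNames(by_name$cbar, by_name$resname))
  } else {
    if (!reference %in% by_name$resname) {
      stop("Reference residue '", reference, "' not present in the cohort.",
        call. = FALSE
      )
    }
    reference
  }
  tab <- cb |>
    dplyr::filter(.data$resname == ref_name) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(cbar_ref = max(.data$cbar), .groups = "drop")
  list(
    table = tab, resname = ref_name,
    how = if (is.null(reference)) "selected by maximal cbar" else "user-named"
  )
}

#' Score residues on the PARCH scale
#'
#' Runs the full pipeline — monotone envelope, autocorrelation, time
#' average, reference standardization, 0-10 scaling — on a tidy table of
#' per-residue water counts, then averages replicates. Normalization is
#' per replicate: each replicate's values are scaled by the reference
#' residue's retention in that same replicate, so the reference scores 10
#' in every replicate (and hence exactly 10 after averaging).
#'
#' @param counts Tidy counts: residue key columns (`chain`, `resid`,
#'   `resname` — any subset), `time_ps`, `count`, and optionally
#'   `replicate`.
#' @param reference How to standardize: `NULL` selects the residue with
#'   maximal replicate-mean retention from the cohort itself (the
#'   calibration choice when scoring the 20 free amino acids); a residue
#'   name (e.g. `"LYS"`) selects that residue; a positive number is used
#'   directly as the reference retention `cbar_ref` for all replicates; a
#'   counts data frame is scored and its best residue used.
#' @param model Water model id recorded in the profile (optional).
#' @param aggregate `"pv"` (default) averages PARCH values across
#'   replicates; `"cbar"` averages retention first and scales once.
#' @param tau_max Autocorrelation lag window; default all lags.
#' @return A `parch_profile`: a tibble with the residue keys and `cbar`
#'   (replicate-mean retention), `pv`, `pv_sd`, `n_replicates`,
#'   `clipped`; attributes record the model and reference provenance.
#' @export
parch_score <- function(counts, reference = NULL, model = NULL,
                        aggregate = c("pv", "cbar"), tau_max = NULL) {
  aggregate <- match.arg(aggregate)
  counts <- validate_counts(counts)
  keys <- residue_key_cols(counts)
  cb <- cbar_table(counts, tau_max = tau_max)
  ref <- resolve_reference(cb, reference, keys)
  scored <- dplyr::left_join(cb, ref$table, by = "replicate")
  if (anyNA(scored$cbar_ref)) {
    stop("No reference value available for some replicates.", call. = FALSE)
  }
  if (any(scored$cbar_ref <= 0)) {
    stop("Invalid reference: nonpositive cbar_ref.", call. = FALSE)
  }
  if (aggregate == "pv") {
    scored$pv_rep <- pmin(10 * scored$cbar / scored$cbar_ref, 10)
    scored$clip_rep <- 10 * scored$cbar / scored$cbar_ref > 10
    prof <- scored |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        cbar = mean(.data$cbar),
        pv = mean(.data$pv_rep),
        pv_sd = stats::sd(.data$pv_rep),
        n_replicates = dplyr::n(),
        clipped = any(.data$clip_rep),
        .groups = "drop"
      )
  } else {
    prof <- scored |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        cbar = mean(.data$cbar),
        cbar_ref = mean(.data$cbar_ref),
        pv_sd = NA_real_,
        n_replicates = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        pv = pmin(10 * .data$cbar / .data$cbar_ref, 10),
        clipped = 10 * .data$cbar / .data$cbar_ref > 10
      ) |>
      dplyr::select(-"cbar_ref") |>
      dplyr::relocate("pv", .after = "cbar")
  }
  if ("resid" %in% keys) prof <- dplyr::arrange(prof, .data$resid)
  new_parch_profile(
    prof,
    model = if (is.null(model)) NA_character_ else normalize_water_model_id(model),
    reference = list(
      resname = ref$resname, how = ref$how,
      cbar_ref = ref$table$cbar_ref
    ),
    aggregate = aggregate
  )
}

new_parch_profile <- function(df, model, reference, aggregate = "pv") {
  structure(
    df,
    class = c("parch_profile", class(df)),
    model = model, reference = reference, aggregate = aggregate
  )
}

#' @export
print.parch_profile <- function(x, ...) {
  ref <- attr(x, "reference")
  cat(
    "<parch_profile> model = ", attr(x, "model"),
    ", reference = ",
    if (is.na(ref$resname)) ref$how else paste0(ref$resname, " (", ref$how, ")"),
    "\n",
    sep = ""
  )
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PARCH profile into a plain tibble
#' @param x A `parch_profile`.
#' @param ... Unused.
#' @return A tibble with one row per residue and a `model` column.
#' @export
tidy.parch_profile <- function(x, ...) {
  out <- tibble::as_tibble(unclass_profile(x))
  out$model <- attr(x, "model")
  out
}

#' One-row summary of a PARCH profile
#' @param x A `parch_profile`.
#' @param ... Unused.
#' @return A one-row tibble: model, residue count, replicate count,
#'   reference residue, mean/min/max PARCH value, number of clipped
#'   residues.
#' @export
glance.parch_profile <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    n_residues = nrow(x),
    n_replicates = max(x$n_replicates),
    reference = attr(x, "reference")$resname,
    pv_mean = mean(x$pv),
    pv_min = min(x$pv),
    pv_max = max(x$pv),
    n_clipped = sum(x$clipped)
  )
}

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), "parch_profile")
  attr(x, "model") <- NULL
  attr(x, "reference") <- NULL
  attr(x, "aggregate") <- NULL
  x
}

#' Average PARCH profiles across replicates
#'
#' Given one profile per annealing replicate (identical residue keys and
#' water model), returns the per-residue arithmetic mean with standard
#' deviation and replicate count. [parch_score()] does this internally
#' when given a `replicate` column; this entry point serves profiles
#' scored separately (e.g. one TSV per run).
#'
#' @param profiles A list of `parch_profile` objects or conforming data
#'   frames with identical residue keys.
#' @return A `parch_profile` of replicate means.
#' @export
aggregate_replicates <- function(profiles) {
  if (length(profiles) == 0L) stop("No profiles supplied.", call. = FALSE)
  keys <- residue_key_cols(profiles[[1]])
  key_str <- function(p) {
    do.call(paste, c(lapply(keys, function(k) p[[k]]), sep = "\r"))
  }
  ref_keys <- sort(key_str(profiles[[1]]))
  for (p in profiles[-1]) {
    if (!identical(sort(key_str(p)), ref_keys)) {
      diff <- c(
        setdiff(key_str(p), ref_keys),
        setdiff(ref_keys, key_str(p))
      )
      stop("Profiles disagree on residue keys: ",
        paste(gsub("\r", "/", utils::head(diff, 5)), collapse = ", "),
        call. = FALSE
      )
    }
  }
  stacked <- dplyr::bind_rows(
    lapply(seq_along(profiles), function(i) {
      p <- tibble::as_tibble(unclass_profile(tibble::as_tibble(profiles[[i]])))
      p$`.rep` <- i
      p
    })
  )
  out <- stacked |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      cbar = if ("cbar" %in% names(stacked)) mean(.data$cbar) else NA_real_,
      pv_sd = stats::sd(.data$pv),
      n_replicates = dplyr::n(),
      clipped = if ("clipped" %in% names(stacked)) any(.data$clipped) else FALSE,
      pv = mean(.data$pv),
      .groups = "drop"
    ) |>
    dplyr::relocate("pv", .after = "cbar")
  model <- attr(profiles[[1]], "model")
  new_parch_profile(
    out,
    model = if (is.null(model)) NA_character_ else model,
    reference = list(
      resname = NA_character_, how = "aggregated profiles",
      cbar_ref = NA_real_
    )
  )
}
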