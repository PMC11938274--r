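# Cross-water-model comparison of PARCH profiles: per-residue signed
# differences against a baseline model (TIP3P by default), residue-class
# groupings, and the ns/*/**/*** significance-star convention used in the
# violin-plot figures.

RESIDUE_CLASSES <- list(
  charged = c("LYS", "ARG", "ASP", "GLU", "HIS"),
  aromatic = c("PHE", "TRP", "TYR"),
  polar = c("SER", "THR", "ASN", "GLN", "CYS"),
  nonpolar = c("ALA", "GLY", "ILE", "LEU", "MET", "PRO", "VAL")
)

#' Chemical class of a residue
#'
#' Fixed default mapping: charged (LYS, ARG, ASP, GLU, HIS — histidine is
#' grouped with the charged residues by default), aromatic (PHE, TRP,
#' TYR), polar (SER, THR, ASN, GLN, CYS), nonpolar (the remainder).
#' Override by passing a modified `classes` list.
#'
#' @param resname Character vector of 3-letter codes.
#' @param classes Named list of code vectors partitioning the 20 standard
#'   amino acids.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_residue(c("LYS", "TRP")) # "charged" "aromatic"
classify_residue <- function(resname, classes = RESIDUE_CLASSES) {
  lut <- stats::setNames(
    rep(names(classes), lengths(classes)),
    unlist(classes, use.names = FALSE)
  )
  out <- lut[toupper(resname)]
  if (anyNA(out)) {
    stop("Unclassifiable residue code(s): ",
      paste(unique(resname[is.na(out)]), collapse = ", "),
      call. = FALSE
    )
  }
  unname(out)
}

#' Significance stars from a p-value
#'
#' The star convention of the comparison figures: `"ns"` for `p > 0.05`,
#' `"*"` for `p <= 0.05`, `"**"` for `p <= 0.01`, `"***"` for
#' `p <= 0.001` (the most significant applicable label; boundaries are
#' inclusive).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare two PARCH value distributions
#'
#' Two-sided rank-based test (Mann-Whitney U, the default — PARCH values
#' are bounded on [0, 10] and not normal) or Welch's t-test, with the
#' star label applied at the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param values_a,values_b Numeric vectors, each of length `>= 2`.
#' @param method `"wilcoxon"` (Mann-Whitney U) or `"welch"`.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `stars`.
#' @export
compare_distributions <- function(values_a, values_b,
                                  method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("Each sample needs at least 2 values.", call. = FALSE)
  }
  ht <- if (method == "wilcoxon") {
    stats::wilcox.test(values_a, values_b, exact = FALSE)
  } else {
    stats::t.test(values_a, values_b)
  }
  tibble::tibble(
    method = method,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    stars = significance_stars(ht$p.value)
  )
}

profile_key_check <- function(profile, baseline) {
  keys <- intersect(residue_key_cols(profile), residue_key_cols(baseline))
  if (length(keys) == 0L) stop("Profiles share no residue key columns.", call. = FALSE)
  key_str <- function(p) do.call(paste, c(lapply(keys, \(k) p[[k]]), sep = "/"))
  ka <- key_str(profile)
  kb <- key_str(baseline)
  extra_a <- setdiff(ka, kb)
  extra_b <- setdiff(kb, ka)
  if (length(extra_a) > 0 || length(extra_b) > 0) {
    stop(
      "Residue keys differ between profiles. Only in first: ",
      paste(utils::head(extra_a, 5), collapse = ", "),
      "; only in baseline: ",
      paste(utils::head(extra_b, 5), collapse = ", "),
      call. = FALSE
    )
  }
  keys
}

#' Per-residue PARCH differences against a baseline model
#'
#' Signed differences `delta_pv = pv_model - pv_baseline` per residue
#' site (the per-site "variance relative to the baseline model"), with
#' the residue class attached when residue names are available.
#'
#' @param profile,baseline `parch_profile`s (or conforming data frames)
#'   over identical residue keys.
#' @return Tibble with the residue keys, `pv`, `pv_baseline`,
#'   `delta_pv`, and `class`; attributes `model` and `baseline_model`.
#' @export
residue_differences <- function(profile, baseline) {
  keys <- profile_key_check(profile, baseline)
  a <- tibble::as_tibble(unclass_profile(tibble::as_tibble(profile)))
  b <- tibble::as_tibble(unclass_profile(tibble::as_tibble(baseline)))
  out <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(keys), pv = "pv"),
    dplyr::select(b, dplyr::all_of(keys), pv_baseline = "pv"),
    by = keys
  ) |>
    dplyr::mutate(delta_pv = .data$pv - .data$pv_baseline)
  if ("resname" %in% keys) {
    std <- out$resname %in% standard_amino_acids()
    out$class <- NA_character_
    out$class[std] <- classify_residue(out$resname[std])
  }
  attr(out, "model") <- attr(profile, "model")
  attr(out, "baseline_model") <- attr(baseline, "model")
  out
}

#' Median PARCH difference per amino-acid type
#'
#' @param differences Output of [residue_differences()].
#' @return Tibble with `resname`, `class`, `n`, `median_delta`.
#' @export
summarize_differences <- function(differences) {
  if (!"resname" %in% names(differences)) {
    stop("Differences lack a 'resname' column.", call. = FALSE)
  }
  differences |>
    dplyr::group_by(.data$resname, .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_delta = stats::median(.data$delta_pv),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$resname)
}

#' Pairwise model comparison of PARCH distributions
#'
#' For every pair of profiles (or every non-baseline model against the
#' baseline when `pairs = "baseline"`), tests whether the PARCH value
#' distributions differ, optionally within residue-class or per-residue
#' groups, and labels each test with significance stars.
#'
#' @param profiles Named list of `parch_profile`s; names are model ids.
#' @param group `"none"` (pooled over all residues), `"class"`, or
#'   `"resname"`.
#' @param pairs `"all"` pairwise, or `"baseline"` (each model vs
#'   `baseline`).
#' @param baseline Baseline model name (default `"TIP3P"`), used when
#'   `pairs = "baseline"`.
#' @param method Test passed to [compare_distributions()].
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw-threshold stars, the
#'   figure convention), `"bonferroni"` available.
#' @return Tibble: `model_a`, `model_b`, `group`, `n_a`, `n_b`,
#'   `p_value`, `stars`.
#' @export
compare_models <- function(profiles, group = c("none", "class", "resname"),
                           pairs = c("all", "baseline"), baseline = "TIP3P",
                           method = c("wilcoxon", "welch"),
                           p_adjust = "none") {
  group <- match.arg(group)
  pairs <- match.arg(pairs)
  method <- match.arg(method)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("'profiles' must be a named list (names = model ids).", call. = FALSE)
  }
  tabs <- lapply(names(profiles), function(m) {
    p <- tibble::as_tibble(unclass_profile(tibble::as_tibble(profiles[[m]])))
    p$model <- m
    if (group == "class") {
      p$group <- classify_residue(p$resname)
    } else if (group == "resname") {
      p$group <- p$resname
    } else {
      p$group <- "all"
    }
    p
  })
  stacked <- dplyr::bind_rows(tabs)
  pair_df <- if (pairs == "all") {
    t(utils::combn(names(profiles), 2L))
  } else {
    if (!baseline %in% names(profiles)) {
      stop("Baseline model '", baseline, "' not among the profiles.",
        call. = FALSE
      )
    }
    cbind(setdiff(names(profiles), baseline), baseline)
  }
  out <- purrr::map_dfr(unique(stacked$group), function(g) {
    sub <- stacked[stacked$group == g, ]
    purrr::map_dfr(seq_len(nrow(pair_df)), function(i) {
      va <- sub$pv[sub$model == pair_df[i, 1]]
      vb <- sub$pv[sub$model == pair_df[i, 2]]
      res <- compare_distributions(va, vb, method = method)
      tibble::tibble(
        model_a = pair_df[i, 1], model_b = pair_df[i, 2], group = g,
        n_a = length(va), n_b = length(vb), p_value = res$p_value
      )
    })
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$stars <- significance_stars(out$p_value)
  out
}

#' Plot a PARCH profile along the sequence
#'
#' Line-and-point plot of PARCH value against residue number, one
#' profile per call or several at once for cross-model overlays.
#'
#' @param object A `parch_profile`.
#' @param ... Further `parch_profile`s to overlay (named arguments
#'   become legend labels).
#' @return A ggplot object.
#' @export
autoplot.parch_profile <- function(object, ...) {
  extras <- list(...)
  profs <- c(list(object), extras)
  labels <- vapply(seq_along(profs), function(i) {
    nm <- if (i == 1L) attr(object, "model") else names(extras)[i - 1L]
    if (is.null(nm) || is.na(nm) || nm == "") paste0("profile ", i) else nm
  }, character(1))
  df <- dplyr::bind_rows(lapply(seq_along(profs), function(i) {
    p <- tidy(profs[[i]])
    p$model <- labels[i]
    p
  }))
  xvar <- if ("resid" %in% names(df)) "resid" else "resname"
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data[[xvar]], y = .data$pv, colour = .data$model)
  ) +
    ggplot2::geom_line(
      if (xvar == "resid") NULL else ggplot2::aes(group = .data$model)
    ) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 10)) +
    ggplot2::labs(
      x = if (xvar == "resid") "residue number" else "residue",
      y = "PARCH value", colour = "water model"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of PARCH distributions across water models
#'
#' @param profiles Named list of `parch_profile`s (names = model ids).
#' @param group `"none"` for one pooled panel, `"class"` to facet by
#'   residue class.
#' @return A ggplot object.
#' @export
plot_model_violins <- function(profiles, group = c("none", "class")) {
  group <- match.arg(group)
  df <- dplyr::bind_rows(lapply(names(profiles), function(m) {
    p <- tibble::as_tibble(unclass_profile(tibble::as_tibble(profiles[[m]])))
    p$model <- m
    p
  }))
  if (group == "class") df$class <- classify_residue(df$resname)
  gg <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$model, y = .data$pv, fill = .data$model)
  ) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::labs(x = "water model", y = "PARCH value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (group == "class") gg <- gg + ggplot2::facet_wrap(~class)
  gg
}
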