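#' Least-squares speed-to-level regression
#'
#' Ordinary least squares of a broadband level (SL or SEL) on speed over
#' ground, optionally per vessel category.
#'
#' @param transits Tibble with `sog_mps` and the response column.
#' @param response Column name of the response, `"sl_db"` or `"sel_db"`.
#' @param by Optional grouping column name (e.g. `"category"`); `NULL` fits
#'   one pooled model.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n` (one row per
#'   group when `by` is given).
#' @export
speed_level_regression <- function(transits, response = "sl_db", by = NULL) {
  fit_one <- function(df) {
    if (nrow(df) < 3) stop("regression needs at least 3 transits")
    if (stats::sd(df$sog_mps) == 0) stop("zero SOG variance; slope undefined")
    m <- stats::lm(stats::reformulate("sog_mps", response), data = df)
    r2 <- if (stats::sd(df[[response]]) == 0) 0 else summary(m)$r.squared
    tibble::tibble(slope = unname(stats::coef(m)[2]),
                   intercept = unname(stats::coef(m)[1]),
                   r_squared = r2,
                   n = nrow(df))
  }
  if (is.null(by)) return(fit_one(transits))
  transits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
}

#' Welch two-sample test between control and rewarded transits
#'
#' Two-sided t-test with unequal variances (Welch). The control and rewarded
#' groups of the transit-by-transit program differ markedly in spread, so the
#' pooled-variance form is not used.
#'
#' @param control,rewarded Numeric vectors of per-transit values (each
#'   length >= 2).
#' @return List with `statistic` (t), `df`, `p_value`, `mean_diff`
#'   (control minus rewarded).
#' @export
transit_by_transit_test <- function(control, rewarded) {
  if (length(control) < 2 || length(rewarded) < 2) {
    stop("both groups need at least 2 transits")
  }
  ht <- stats::t.test(control, rewarded, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = mean(control) - mean(rewarded))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

# Tie-corrected Dunn z statistic for one pair of cells, using ranks over the
# pooled sample. No pre-installed package provides Dunn's test, so the
# standard form is implemented here:
#   z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - C) (1/n_i + 1/n_j)),
#   C = sum(t^3 - t) / (12 (N - 1)) over tie groups of size t.
dunn_pair <- function(rbar_i, rbar_j, n_i, n_j, n_total, tie_term) {
  se <- sqrt((n_total * (n_total + 1) / 12 - tie_term) * (1 / n_i + 1 / n_j))
  (rbar_i - rbar_j) / se
}

#' Tier-by-phase comparison: Kruskal-Wallis, Dunn post-hoc, BH adjustment
#'
#' Omnibus Kruskal-Wallis test across all award-tier-by-program-phase cells,
#' followed by Dunn's pairwise z-tests over the comparison family of
#' interest: every tier pair within each phase, plus each tier compared with
#' itself across phases. Raw two-sided p-values are adjusted with the
#' Benjamini-Hochberg step-up procedure over the whole family (one response
#' variable per call; run separately for SOG, SL and SEL). Mean differences
#' are reported alongside the tests.
#'
#' @param values Numeric vector of per-transit values.
#' @param tier Character vector of award tiers, same length.
#' @param phase Character vector of program phases, same length.
#' @return List with `kruskal` (`statistic`, `df`, `p_value`) and
#'   `comparisons`, a tibble with `tier_1`, `phase_1`, `tier_2`, `phase_2`,
#'   `mean_diff`, `z`, `p_value`, `p_adjusted`, `significance`.
#' @export
tier_comparison <- function(values, tier, phase) {
  stopifnot(length(values) == length(tier), length(values) == length(phase))
  cell <- paste(tier, phase, sep = ".")
  counts <- table(cell)
  if (any(counts == 0) || length(counts) < 2) {
    stop("need at least two non-empty tier-phase cells")
  }
  kw <- stats::kruskal.test(values, factor(cell))

  n_total <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  cells <- tibble::tibble(cell = names(counts)) |>
    tidyr_separate_cell()
  rbar <- tapply(rk, cell, mean)
  mns <- tapply(values, cell, mean)
  ns <- as.numeric(counts)
  names(ns) <- names(counts)

  # family: tiers within a phase + phases within a tier
  pairs <- list()
  for (ph in unique(cells$phase)) {
    tiers_ph <- cells$cell[cells$phase == ph]
    if (length(tiers_ph) >= 2) {
      cmb <- utils::combn(sort(tiers_ph), 2)
      for (k in seq_len(ncol(cmb))) pairs[[length(pairs) + 1]] <- cmb[, k]
    }
  }
  for (ti in unique(cells$tier)) {
    cells_ti <- cells$cell[cells$tier == ti]
    if (length(cells_ti) >= 2) {
      cmb <- utils::combn(sort(cells_ti), 2)
      for (k in seq_len(ncol(cmb))) pairs[[length(pairs) + 1]] <- cmb[, k]
    }
  }

  comp <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    z <- dunn_pair(rbar[[a]], rbar[[b]], ns[[a]], ns[[b]], n_total, tie_term)
    tibble::tibble(
      tier_1 = sub("\\.[^.]+$", "", a),
      phase_1 = sub("^.*\\.", "", a),
      tier_2 = sub("\\.[^.]+$", "", b),
      phase_2 = sub("^.*\\.", "", b),
      mean_diff = mns[[a]] - mns[[b]],
      z = z,
      p_value = 2 * stats::pnorm(-abs(z))
    )
  }) |> dplyr::bind_rows()
  comp$p_adjusted <- stats::p.adjust(comp$p_value, method = "BH")
  comp$significance <- significance_stars(comp$p_adjusted)

  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       comparisons = comp)
}

tidyr_separate_cell <- function(df) {
  df$tier <- sub("\\.[^.]+$", "", df$cell)
  df$phase <- sub("^.*\\.", "", df$cell)
  df
}

#' Per-group summary of a transit results table
#'
#' Mirrors the reporting layout of the group tables: transit count and
#' mean +/- SD of SOG and of each broadband level present in the table.
#'
#' @param results Tibble with a grouping column and numeric columns among
#'   `sog_mps`, `rl_db`, `sl_db`, `sel_db`, `duration_s`, `source_depth_m`.
#' @param by Grouping column name(s), default `"group"`.
#' @return Tibble: one row per group with `n` and `<col>_mean` / `<col>_sd`
#'   columns.
#' @export
summarize_groups <- function(results, by = "group") {
  num_cols <- intersect(c("sog_mps", "rl_db", "sl_db", "sel_db",
                          "duration_s", "source_depth_m"),
                        names(results))
  sd0 <- function(x) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = TRUE)
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols),
                    list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd0(.x))),
      .groups = "drop"
    )
}

#' Greatest between-group difference in a summary table
#'
#' @param summary_tbl Output of [summarize_groups()].
#' @param column Mean column to compare, e.g. `"sl_db_mean"`.
#' @return One-row tibble with the two group labels and the absolute
#'   difference of their means.
#' @export
greatest_difference <- function(summary_tbl, column) {
  v <- summary_tbl[[column]]
  hi <- which.max(v); lo <- which.min(v)
  lab <- summary_tbl[[1]]
  tibble::tibble(group_high = lab[hi], group_low = lab[lo],
                 difference = v[hi] - v[lo])
}
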