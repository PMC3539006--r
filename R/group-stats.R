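# Null permutation distribution of the mid-rank U statistic: U values for
# every C(n, n_A) assignment of the pooled ranks to group A.
u_permutation_distribution <- function(ranks, n_A) {
  idx <- utils::combn(length(ranks), n_A)
  colSums(matrix(ranks[idx], nrow = n_A)) - n_A * (n_A + 1) / 2
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided rank test for a location difference between two independent
#' groups. `U` is computed from mid-ranks (ties share the average rank). For
#' small samples (`n_A + n_B <= exact_limit`) the two-sided p-value is exact:
#' all `choose(n_A + n_B, n_A)` assignments of the pooled ranks to group A
#' are enumerated and `p = P(|U - n_A n_B / 2| >= |U_obs - n_A n_B / 2|)`
#' under that permutation null. Larger samples use the normal approximation
#' with tie-corrected variance and a continuity correction of 1/2.
#'
#' @param group_A,group_B Numeric vectors, each non-empty.
#' @param method `"auto"` (exact when the pooled size allows), `"exact"` or
#'   `"normal"`.
#' @param exact_limit Largest pooled sample size for which `"auto"`
#'   enumerates (default 16).
#' @return An object of class `group_comparison`: a list with `n_A`, `n_B`,
#'   `U` (for group A), `p_two_sided`, `method` used
#'   (`"exact_enumeration"` or `"normal_approx_tie_corrected"`),
#'   `degenerate` (TRUE when all pooled values are identical, forcing p = 1),
#'   and group summaries `mean_A`, `mean_B`, `sd_A`, `sd_B`,
#'   `mean_difference` (= mean_A - mean_B).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney_u <- function(group_A, group_B,
                           method = c("auto", "exact", "normal"),
                           exact_limit = 16L) {
  method <- match.arg(method)
  group_A <- as.numeric(group_A)
  group_B <- as.numeric(group_B)
  if (length(group_A) < 1 || length(group_B) < 1) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  if (any(!is.finite(group_A)) || any(!is.finite(group_B))) {
    stop("group values must be finite", call. = FALSE)
  }
  n_A <- length(group_A)
  n_B <- length(group_B)
  n <- n_A + n_B
  pooled <- c(group_A, group_B)
  ranks <- rank(pooled)
  U <- sum(ranks[seq_len(n_A)]) - n_A * (n_A + 1) / 2
  mu <- n_A * n_B / 2

  degenerate <- length(unique(pooled)) == 1L
  use_exact <- switch(method,
    auto = n <= exact_limit,
    exact = TRUE,
    normal = FALSE
  )

  if (degenerate) {
    p <- 1
    used <- if (use_exact) "exact_enumeration" else "normal_approx_tie_corrected"
  } else if (use_exact) {
    perm <- u_permutation_distribution(ranks, n_A)
    # fuzz guards mid-rank halves against floating-point representation
    p <- mean(abs(perm - mu) >= abs(U - mu) - 1e-9)
    used <- "exact_enumeration"
  } else {
    tie_counts <- table(pooled)
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sigma2 <- n_A * n_B / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      degenerate <- TRUE
    } else {
      z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-z), 1)
    }
    used <- "normal_approx_tie_corrected"
  }

  structure(list(
    n_A = n_A, n_B = n_B, U = U, p_two_sided = p, method = used,
    degenerate = degenerate,
    mean_A = mean(group_A), mean_B = mean(group_B),
    sd_A = if (n_A > 1) stats::sd(group_A) else NA_real_,
    sd_B = if (n_B > 1) stats::sd(group_B) else NA_real_,
    mean_difference = mean(group_A) - mean(group_B)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %.1f (n = %d vs %d), two-sided p = %.4g [%s]%s\n",
    x$U, x$n_A, x$n_B, x$p_two_sided, x$method,
    if (isTRUE(x$degenerate)) " (degenerate: all values identical)" else ""
  ))
  if (!is.null(x$variable)) {
    cat(sprintf("  %s: mean difference %.3f (%.3f vs %.3f)\n",
                x$variable, x$mean_difference, x$mean_A, x$mean_B))
  }
  invisible(x)
}

contrast_variables <- c("d15N", "d13C", "N_wt_pct", "C_wt_pct", "CN_ratio")

#' Contrast whole-lichen measurements between substrate classes
#'
#' Tests whether whole-lichen specimens from minerogenic substrates differ
#' from those on organic substrates in the chosen variable, using
#' [mann_whitney_u()]. The reported `mean_difference` is
#' mean(minerogenic) - mean(organic), i.e. a positive value is an enrichment
#' on minerogenic substrate.
#'
#' @param records A validated specimen tibble with whole-lichen rows from
#'   both substrate classes.
#' @param variable One of `"d15N"`, `"d13C"`, `"N_wt_pct"`, `"C_wt_pct"`,
#'   `"CN_ratio"`.
#' @param ... Passed to [mann_whitney_u()].
#' @return A `group_comparison` with group A = minerogenic, group B =
#'   organic, and the variable name attached.
#' @export
substrate_contrast <- function(records, variable = contrast_variables, ...) {
  variable <- match.arg(variable)
  records <- validate_specimens(records)
  records <- records[records$tissue == "whole_lichen", ]
  vals <- records[[variable]]
  keep <- !is.na(vals)
  a <- vals[keep & records$substrate_class == "minerogenic"]
  b <- vals[keep & records$substrate_class == "organic"]
  if (length(a) == 0 || length(b) == 0) {
    stop("both substrate classes must be present among whole-lichen records",
         call. = FALSE)
  }
  cmp <- mann_whitney_u(a, b, ...)
  cmp$variable <- variable
  cmp$group_A_label <- "minerogenic"
  cmp$group_B_label <- "organic"
  cmp
}

#' Grouped summary statistics
#'
#' Per-group n, mean, sample SD (n - 1 denominator, `NA` for singleton
#' groups), minimum and maximum for one measured variable, grouped by
#' substrate class or tissue.
#'
#' @inheritParams substrate_contrast
#' @param group_by `"substrate_class"` or `"tissue"`.
#' @param tissue Optional tissue filter applied before summarising (ignored
#'   when grouping by tissue).
#' @return A tibble with columns `group`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
grouped_summary <- function(records, variable = contrast_variables,
                            group_by = c("substrate_class", "tissue"),
                            tissue = NULL) {
  variable <- match.arg(variable)
  group_by <- match.arg(group_by)
  records <- validate_specimens(records)
  if (!is.null(tissue) && group_by != "tissue") {
    records <- records[records$tissue %in% tissue, ]
  }
  vals <- records[[variable]]
  keep <- !is.na(vals)
  records <- records[keep, ]
  vals <- vals[keep]
  if (nrow(records) == 0) stop("no non-missing values to summarise", call. = FALSE)
  tibble::tibble(group = records[[group_by]], value = vals) |>
    dplyr::group_by(group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(value),
      sd = if (dplyr::n() > 1) stats::sd(value) else NA_real_,
      min = min(value),
      max = max(value),
      .groups = "drop"
    )
}

#' Pairwise correlation of biont isotope values across populations
#'
#' For matched populations, tests whether the photobiont's isotope value
#' tracks the mycobiont's (Pearson correlation, two-sided), separately for
#' delta15N and delta13C. In the study system the delta13C values correlate
#' (carbon flows from photobiont to mycobiont) while the delta15N values do
#' not (independent nitrogen acquisition).
#'
#' @param triplets Output of [group_triplets()], at least 3 rows.
#' @param alpha Significance level used for the `significant` flag.
#' @return A tibble with one row per isotope: `isotope`, `n`, `r`, `p`,
#'   `significant`, `degenerate` (TRUE when a variable has zero variance, in
#'   which case `r` and `p` are `NA`).
#' @export
biont_correlation <- function(triplets, alpha = 0.05) {
  if (nrow(triplets) < 3) {
    stop("at least 3 population triplets are required", call. = FALSE)
  }
  one <- function(iso, px, mx) {
    keep <- !is.na(px) & !is.na(mx)
    px <- px[keep]; mx <- mx[keep]
    if (length(px) < 3 || stats::sd(px) == 0 || stats::sd(mx) == 0) {
      return(tibble::tibble(isotope = iso, n = length(px), r = NA_real_,
                            p = NA_real_, significant = NA, degenerate = TRUE))
    }
    ct <- stats::cor.test(px, mx, method = "pearson")
    tibble::tibble(isotope = iso, n = length(px), r = unname(ct$estimate),
                   p = ct$p.value, significant = ct$p.value < alpha,
                   degenerate = FALSE)
  }
  dplyr::bind_rows(
    one("d15N", triplets$d15N_P, triplets$d15N_M),
    one("d13C", triplets$d13C_P, triplets$d13C_M)
  )
}

#' Render a set of substrate contrasts as CSV and text
#'
#' @param contrasts A list of `group_comparison` objects (e.g. one per
#'   variable).
#' @return A tibble with one row per comparison.
#' @export
contrast_table <- function(contrasts) {
  dplyr::bind_rows(lapply(contrasts, function(cmp) {
    tibble::tibble(
      variable = cmp$variable %||% NA_character_,
      n_minerogenic = cmp$n_A, n_organic = cmp$n_B,
      U = cmp$U, p_two_sided = cmp$p_two_sided, method = cmp$method,
      mean_minerogenic = cmp$mean_A, mean_organic = cmp$mean_B,
      sd_minerogenic = cmp$sd_A, sd_organic = cmp$sd_B,
      mean_difference = cmp$mean_difference
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
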