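#' Define a pair of isotopic end-members
#'
#' A two-end-member nitrogen mixing system is fully described by the
#' mycobiont and photobiont delta15N values and their nitrogen contents.
#' Because a whole-lichen measurement mixes nitrogen, not biomass, the
#' nitrogen contents weight the biomass fractions; only the ratio
#' `N_P / N_M` matters for every model output, so any consistent unit
#' (wt%, mg/g, ...) may be used.
#'
#' @param d15N_M Mycobiont delta15N (per mil vs AIR).
#' @param d15N_P Photobiont delta15N (per mil vs AIR).
#' @param N_M Mycobiont nitrogen content (> 0, any consistent unit).
#' @param N_P Photobiont nitrogen content (> 0, same unit).
#' @return An object of class `end_members`.
#' @examples
#' end_members(d15N_M = -4.2, d15N_P = -15.7, N_M = 0.82, N_P = 3.5)
#' @export
end_members <- function(d15N_M, d15N_P, N_M, N_P) {
  vals <- c(d15N_M = d15N_M, d15N_P = d15N_P, N_M = N_M, N_P = N_P)
  if (!all(is.finite(vals))) {
    stop("end-member values must be finite numbers", call. = FALSE)
  }
  if (N_M <= 0 || N_P <= 0) {
    stop("end-member nitrogen contents must be > 0", call. = FALSE)
  }
  structure(
    list(d15N_M = d15N_M, d15N_P = d15N_P, N_M = N_M, N_P = N_P),
    class = "end_members"
  )
}

#' @export
print.end_members <- function(x, ...) {
  cat(sprintf(
    "two-end-member system: mycobiont %.2f permil (N %.3g), photobiont %.2f permil (N %.3g)\n",
    x$d15N_M, x$N_M, x$d15N_P, x$N_P
  ))
  invisible(x)
}

check_fraction <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("biomass fraction f_M_B must lie in [0, 1]", call. = FALSE)
  }
}

#' Fractional nitrogen contributions of the two bionts
#'
#' Converts a mycobiont biomass fraction into the fraction of whole-lichen
#' nitrogen each biont contributes, weighting biomass by nitrogen content:
#' \deqn{f_{M,N} = \frac{f_{M,B} [N]_M}{f_{M,B} [N]_M + (1 - f_{M,B}) [N]_P}}
#' and \eqn{f_{P,N} = 1 - f_{M,N}} exactly.
#'
#' @param f_M_B Mycobiont biomass fraction(s) in \[0, 1\].
#' @param pair An [end_members()] object.
#' @return A tibble with columns `f_M_N` and `f_P_N` (rows follow `f_M_B`).
#' @export
nitrogen_fractions <- function(f_M_B, pair) {
  stopifnot(inherits(pair, "end_members"))
  check_fraction(f_M_B)
  f_M_N <- f_M_B * pair$N_M / (f_M_B * pair$N_M + (1 - f_M_B) * pair$N_P)
  tibble::tibble(f_M_N = f_M_N, f_P_N = 1 - f_M_N)
}

#' Forward mixing model: whole-lichen delta15N from biomass fraction
#'
#' The whole-lichen delta15N is the nitrogen-fraction-weighted mean of the
#' two end-member values,
#' \deqn{\delta^{15}N_L = f_{M,N}\,\delta^{15}N_M + f_{P,N}\,\delta^{15}N_P,}
#' with nitrogen fractions from [nitrogen_fractions()]. The curve is the
#' nonlinear "mixing line": straight only when the two nitrogen contents are
#' equal, and strictly monotone in `f_M_B` whenever the end-member delta15N
#' values differ.
#'
#' @inheritParams nitrogen_fractions
#' @return Whole-lichen delta15N value(s) in per mil.
#' @examples
#' pair <- end_members(d15N_M = -4, d15N_P = -16, N_M = 1, N_P = 4)
#' forward_d15N(c(0, 0.9, 1), pair)
#' @export
forward_d15N <- function(f_M_B, pair) {
  fr <- nitrogen_fractions(f_M_B, pair)
  fr$f_M_N * pair$d15N_M + fr$f_P_N * pair$d15N_P
}

#' Closed-form inversion of the mixing model
#'
#' Algebraic rearrangement of the forward model giving the mycobiont biomass
#' fraction that reproduces an observed whole-lichen delta15N:
#' \deqn{f_{M,B} = \frac{[N]_P (\delta_L - \delta_P)}
#'   {[N]_M (\delta_M - \delta_L) + [N]_P (\delta_L - \delta_P)}.}
#' The value is unclamped: observations outside the end-member interval
#' (possible under measurement noise) yield values outside \[0, 1\]. This
#' serves as the independent oracle for the iterative fit in
#' [invert_f_M_B()].
#'
#' @param d15N_L_obs Observed whole-lichen delta15N (per mil).
#' @param pair An [end_members()] object; its two delta15N values must differ.
#' @return Unclamped biomass fraction(s).
#' @export
closed_form_f_M_B <- function(d15N_L_obs, pair) {
  stopifnot(inherits(pair, "end_members"))
  if (pair$d15N_M == pair$d15N_P) {
    stop("end-member delta15N values are identical: the biomass fraction is unidentifiable",
         call. = FALSE)
  }
  num <- pair$N_P * (d15N_L_obs - pair$d15N_P)
  den <- pair$N_M * (pair$d15N_M - d15N_L_obs) + num
  if (any(den == 0)) {
    stop("degenerate observation: inversion denominator is zero (unidentifiable)",
         call. = FALSE)
  }
  num / den
}

#' Iterative inversion of the mixing model
#'
#' Finds the mycobiont biomass fraction whose forward-modelled whole-lichen
#' delta15N matches the observed value, by bisection on \[0, 1\] (the forward
#' model is continuous and strictly monotone there). Observations outside the
#' interval spanned by the end-members are clamped to the nearer endpoint
#' with an explicit status, so survey-scale runs complete and the residual
#' records the unexplained gap.
#'
#' @param d15N_L_obs Observed whole-lichen delta15N (per mil), scalar.
#' @param pair An [end_members()] object with distinct delta15N values.
#' @param tolerance Convergence tolerance on the fitted delta15N, per mil.
#' @param max_iter Maximum bisection iterations.
#' @return An object of class `mixing_solution`: a list with `f_M_B`,
#'   `f_P_B` (= 1 - `f_M_B` exactly), `f_M_N`, `f_P_N` (summing to 1
#'   exactly), `d15N_L_fit`, `residual` (observed - fitted), `status`
#'   (`"converged"`, `"clamped_low"` or `"clamped_high"`) and `iterations`.
#' @examples
#' pair <- end_members(d15N_M = -4, d15N_P = -16, N_M = 1, N_P = 4)
#' invert_f_M_B(-7.6923, pair)
#' @export
invert_f_M_B <- function(d15N_L_obs, pair, tolerance = 1e-10, max_iter = 200L) {
  stopifnot(inherits(pair, "end_members"), length(d15N_L_obs) == 1L)
  if (!is.finite(d15N_L_obs)) stop("observed delta15N must be finite", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (pair$d15N_M == pair$d15N_P) {
    stop("end-member delta15N values are identical: the biomass fraction is unidentifiable",
         call. = FALSE)
  }
  lo_val <- min(pair$d15N_P, pair$d15N_M)
  hi_val <- max(pair$d15N_P, pair$d15N_M)

  finish <- function(f, status, iterations) {
    fr <- nitrogen_fractions(f, pair)
    fit <- fr$f_M_N * pair$d15N_M + fr$f_P_N * pair$d15N_P
    structure(list(
      f_M_B = f, f_P_B = 1 - f,
      f_M_N = fr$f_M_N, f_P_N = fr$f_P_N,
      d15N_L_fit = fit, residual = d15N_L_obs - fit,
      status = status, iterations = iterations
    ), class = "mixing_solution")
  }

  if (d15N_L_obs < lo_val || d15N_L_obs > hi_val) {
    # which endpoint is nearer in delta terms decides the clamp side
    near_P <- abs(d15N_L_obs - pair$d15N_P) <= abs(d15N_L_obs - pair$d15N_M)
    f <- if (near_P) 0 else 1
    return(finish(f, if (near_P) "clamped_low" else "clamped_high", 0L))
  }

  g <- function(f) forward_d15N(f, pair) - d15N_L_obs
  lo <- 0; hi <- 1
  g_lo <- g(lo)
  g_hi <- g(hi)
  if (abs(g_lo) <= tolerance) return(finish(lo, "converged", 0L))
  if (abs(g_hi) <= tolerance) return(finish(hi, "converged", 0L))
  iter <- 0L
  mid <- 0.5
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    if (abs(g_mid) <= tolerance || (hi - lo) / 2 < .Machine$double.eps) {
      return(finish(mid, "converged", iter))
    }
    if ((g_mid > 0) == (g_lo > 0)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid
    }
  }
  finish(mid, "converged", iter)
}

#' @export
print.mixing_solution <- function(x, ...) {
  cat(sprintf(
    "mixing solution: f_M_B = %.4f (f_P_B = %.4f), f_M_N = %.4f, fitted %.3f permil, residual %.2e, %s in %d iterations\n",
    x$f_M_B, x$f_P_B, x$f_M_N, x$d15N_L_fit, x$residual, x$status, x$iterations
  ))
  invisible(x)
}

#' Evaluate a mixing line over the biomass-fraction range
#'
#' Sweeps the mycobiont biomass fraction over an even grid on \[0, 1\] and
#' evaluates the forward model, producing the nonlinear curve whose endpoints
#' are the photobiont (f = 0) and mycobiont (f = 1) delta15N values.
#'
#' @param pair An [end_members()] object.
#' @param n_points Number of grid points (>= 2).
#' @return A tibble with columns `f_M_B` and `d15N_L`, of class
#'   `mixing_line`, with the end-member pair attached as attribute `"pair"`.
#' @export
mixing_line <- function(pair, n_points = 101L) {
  stopifnot(inherits(pair, "end_members"))
  if (!is.numeric(n_points) || n_points < 2) {
    stop("n_points must be at least 2", call. = FALSE)
  }
  f <- seq(0, 1, length.out = as.integer(n_points))
  out <- tibble::tibble(f_M_B = f, d15N_L = forward_d15N(f, pair))
  attr(out, "pair") <- pair
  class(out) <- c("mixing_line", class(out))
  out
}

#' Partition biomass for a set of matched populations
#'
#' Applies the inverse mixing model population by population, each with its
#' own biont end-members (nitrogen contents are never pooled across
#' populations), and summarises the recovered mycobiont biomass fractions by
#' substrate class. Populations whose bionts share a delta15N value are
#' unidentifiable; they are excluded from the summary and reported, never
#' silently dropped.
#'
#' @param triplets Output of [group_triplets()] (or the `triplets` element of
#'   a synthetic dataset).
#' @param tolerance,max_iter Passed to [invert_f_M_B()].
#' @return An object of class `partition_result`: a list with
#'   `solutions` (tibble: population_id, substrate_class, f_M_B, f_P_B,
#'   f_M_N, f_P_N, d15N_L_fit, residual, status, iterations),
#'   `summary` (tibble per substrate class: n, mean_f_M_B, sd_f_M_B,
#'   n_clamped) and `unidentifiable` (tibble of excluded populations).
#' @export
partition_populations <- function(triplets, tolerance = 1e-10, max_iter = 200L) {
  if (nrow(triplets) < 1) stop("at least one population triplet is required", call. = FALSE)
  sol <- vector("list", nrow(triplets))
  unident <- list()
  for (i in seq_len(nrow(triplets))) {
    tr <- triplets[i, ]
    if (tr$d15N_M == tr$d15N_P) {
      unident[[length(unident) + 1]] <- tibble::tibble(
        population_id = tr$population_id,
        reason = "identical biont delta15N values: unidentifiable"
      )
      next
    }
    pair <- end_members(tr$d15N_M, tr$d15N_P, tr$N_M, tr$N_P)
    s <- invert_f_M_B(tr$d15N_L, pair, tolerance = tolerance, max_iter = max_iter)
    sol[[i]] <- tibble::tibble(
      population_id = tr$population_id,
      substrate_class = tr$substrate_class,
      f_M_B = s$f_M_B, f_P_B = s$f_P_B,
      f_M_N = s$f_M_N, f_P_N = s$f_P_N,
      d15N_L_fit = s$d15N_L_fit, residual = s$residual,
      status = s$status, iterations = s$iterations
    )
  }
  solutions <- dplyr::bind_rows(sol)
  if (nrow(solutions) == 0) {
    stop("no identifiable populations: every triplet has identical biont delta15N values",
         call. = FALSE)
  }
  summary <- solutions |>
    dplyr::group_by(substrate_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_f_M_B = mean(f_M_B),
      sd_f_M_B = if (dplyr::n() > 1) stats::sd(f_M_B) else NA_real_,
      n_clamped = sum(status != "converged"),
      .groups = "drop"
    )
  structure(list(
    solutions = solutions,
    summary = summary,
    unidentifiable = if (length(unident) > 0) dplyr::bind_rows(unident) else
      tibble::tibble(population_id = character(), reason = character())
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("biomass partition for", nrow(x$solutions), "population(s)\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: n = %d, f_M_B = %.3f +/- %.3f (%d clamped)\n",
                s$substrate_class, s$n, s$mean_f_M_B,
                ifelse(is.na(s$sd_f_M_B), 0, s$sd_f_M_B), s$n_clamped))
  }
  if (nrow(x$unidentifiable) > 0) {
    cat("  unidentifiable populations:",
        paste(x$unidentifiable$population_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write partition solutions and per-population mixing lines to CSV
#'
#' `write_partition()` writes one row per population (plus the summary file
#' alongside it); `write_mixing_lines()` evaluates one mixing line per
#' population on a shared f grid, in long format suitable for replotting.
#'
#' @param x A `partition_result`.
#' @param path Output CSV path for the solutions; the summary is written next
#'   to it with suffix `_summary.csv`.
#' @return The path, invisibly.
#' @export
write_partition <- function(x, path) {
  stopifnot(inherits(x, "partition_result"))
  readr::write_csv(x$solutions, path, progress = FALSE)
  sum_path <- sub("\\.csv$", "_summary.csv", path)
  if (identical(sum_path, path)) sum_path <- paste0(path, "_summary.csv")
  readr::write_csv(x$summary, sum_path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param triplets Output of [group_triplets()].
#' @param n_points Grid resolution per line.
#' @export
write_mixing_lines <- function(triplets, path, n_points = 101L) {
  lines <- lapply(seq_len(nrow(triplets)), function(i) {
    tr <- triplets[i, ]
    if (tr$d15N_M == tr$d15N_P) return(NULL)
    ml <- mixing_line(end_members(tr$d15N_M, tr$d15N_P, tr$N_M, tr$N_P),
                      n_points = n_points)
    tibble::tibble(
      population_id = tr$population_id,
      substrate_class = tr$substrate_class,
      f_M_B = ml$f_M_B, d15N_L = ml$d15N_L
    )
  })
  readr::write_csv(dplyr::bind_rows(lines), path, progress = FALSE)
  invisible(path)
}
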