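# Mean of a normal(mu, sd) truncated to [a, b].
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / max(Z, .Machine$double.xmin)
}

# Parent mean whose truncated distribution has the requested mean. Truncation
# at finite bounds pulls the realised mean toward the interval centre; the
# generator compensates so configured means are reproduced exactly.
match_parent_mean <- function(target, sd, a, b) {
  if (sd == 0 || (is.infinite(a) && is.infinite(b))) return(target)
  lo <- if (is.finite(a)) a - 8 * sd else target - 8 * sd
  hi <- if (is.finite(b)) b + 8 * sd else target + 8 * sd
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, a, b) - target,
                 interval = c(lo, hi), tol = 1e-12)$root
}

# Truncated-normal sampler (rejection from the parent normal). The parent
# mean is moment-matched so that E[X] equals `mean` after truncation.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (lower >= upper) {
    stop(sprintf("infeasible truncation interval [%g, %g]", lower, upper),
         call. = FALSE)
  }
  if (mean < lower || mean > upper) {
    stop(sprintf("truncation interval [%g, %g] must contain the mean %g",
                 lower, upper, mean), call. = FALSE)
  }
  if (sd == 0) return(rep(mean, n))
  mu <- match_parent_mean(mean, sd, lower, upper)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(n, mu, sd)
    out <- c(out, cand[cand >= lower & cand <= upper])
  }
  out[seq_len(n)]
}

default_truncation_ranges <- list(
  photobiont_d15N = c(-20.7, -12.6),
  mycobiont_d15N = c(-10.6, 0.2),
  photobiont_d13C = c(-28.1, -22.5),
  mycobiont_d13C = c(-23.5, -20.5),
  photobiont_CN = c(4.5, 21.3),
  mycobiont_CN = c(7.0, 103.0),
  f_M_B = c(0, 1)
)

ms <- function(mean, sd) list(mean = mean, sd = sd)

#' Configuration for the synthetic lichen-isotope generator
#'
#' Parameterises surveys and biont-separation datasets with the statistical
#' structure the analysis assumes. Defaults are the study conditions: biont
#' delta15N/delta13C and C/N summaries per substrate class, mycobiont
#' biomass fractions of 0.90 +/- 0.09 (organic) and 0.94 +/- 0.02
#' (minerogenic), 38 organic vs 44 minerogenic survey specimens and 10
#' separated populations. Values are drawn from truncated normal
#' distributions bounded by the observed ranges; nitrogen contents are
#' derived from C/N assuming equal carbon content in both bionts
#' (`carbon_wt_pct`, default 45 wt%).
#'
#' @param n_organic,n_minerogenic Survey specimen counts per substrate class.
#' @param n_populations Number of biont-separation populations (split evenly
#'   between substrate classes, the extra one organic when odd).
#' @param photobiont_d15N,mycobiont_d15N Per-substrate `list(organic =
#'   list(mean=, sd=), minerogenic = list(mean=, sd=))` delta15N parameters
#'   (per mil).
#' @param photobiont_d13C,mycobiont_d13C `list(mean=, sd=)` delta13C
#'   parameters (per mil), shared across substrates.
#' @param photobiont_CN,mycobiont_CN `list(mean=, sd=)` mass-based C/N
#'   parameters.
#' @param f_M_B Per-substrate `list(mean=, sd=)` true mycobiont biomass
#'   fractions, truncated to (0, 1).
#' @param carbon_wt_pct Carbon mass fraction (wt%) applied to both bionts;
#'   converts C/N to nitrogen content.
#' @param measurement_noise_sd Additive Gaussian noise on whole-lichen delta
#'   values (per mil), emulating instrument precision.
#' @param d13C_substrate_shift Per-mil offset added to minerogenic
#'   whole-lichen delta13C. This reproduces the observed survey-level
#'   delta13C enrichment on minerogenic substrate, which the nitrogen mixing
#'   model does not generate; it is an emulation device, not part of the
#'   mass-balance model.
#' @param truncation_ranges Named list of `c(min, max)` bounds per variable;
#'   see `lichenmix:::default_truncation_ranges` for the defaults (observed
#'   ranges for the isotope values, mean +/- 3 SD clipped positive for C/N).
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(
    n_organic = 38L,
    n_minerogenic = 44L,
    n_populations = 10L,
    photobiont_d15N = list(organic = ms(-15.8, 2.6), minerogenic = ms(-15.7, 3.1)),
    mycobiont_d15N = list(organic = ms(-7.7, 1.9), minerogenic = ms(-4.2, 4.0)),
    photobiont_d13C = ms(-25.4, 1.7),
    mycobiont_d13C = ms(-22.0, 1.1),
    photobiont_CN = ms(12.9, 2.8),
    mycobiont_CN = ms(55.0, 16.0),
    f_M_B = list(organic = ms(0.90, 0.09), minerogenic = ms(0.94, 0.02)),
    carbon_wt_pct = 45.0,
    measurement_noise_sd = 0.2,
    d13C_substrate_shift = 2.6,
    truncation_ranges = default_truncation_ranges,
    seed = 1L) {
  cfg <- list(
    n_organic = as.integer(n_organic),
    n_minerogenic = as.integer(n_minerogenic),
    n_populations = as.integer(n_populations),
    photobiont_d15N = photobiont_d15N,
    mycobiont_d15N = mycobiont_d15N,
    photobiont_d13C = photobiont_d13C,
    mycobiont_d13C = mycobiont_d13C,
    photobiont_CN = photobiont_CN,
    mycobiont_CN = mycobiont_CN,
    f_M_B = f_M_B,
    carbon_wt_pct = as.numeric(carbon_wt_pct),
    measurement_noise_sd = as.numeric(measurement_noise_sd),
    d13C_substrate_shift = as.numeric(d13C_substrate_shift),
    truncation_ranges = utils::modifyList(default_truncation_ranges,
                                          lapply(truncation_ranges, as.numeric)),
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_organic < 0 || cfg$n_minerogenic < 0 || cfg$n_populations < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (cfg$carbon_wt_pct <= 0) stop("carbon_wt_pct must be > 0", call. = FALSE)
  if (cfg$measurement_noise_sd < 0) {
    stop("measurement_noise_sd must be >= 0", call. = FALSE)
  }
  per_sub <- c("photobiont_d15N", "mycobiont_d15N", "f_M_B")
  shared <- c("photobiont_d13C", "mycobiont_d13C", "photobiont_CN", "mycobiont_CN")
  get_ms <- function(x, what) {
    if (!is.list(x) || !all(c("mean", "sd") %in% names(x))) {
      stop(what, " must be a list with elements mean and sd", call. = FALSE)
    }
    c(mean = as.numeric(x$mean), sd = as.numeric(x$sd))
  }
  check_ms <- function(p, range_key, what) {
    if (p[["sd"]] < 0) stop(what, ": sd must be >= 0", call. = FALSE)
    r <- cfg$truncation_ranges[[range_key]]
    if (r[1] >= r[2]) {
      stop(what, sprintf(": infeasible truncation interval [%g, %g]", r[1], r[2]),
           call. = FALSE)
    }
    if (p[["mean"]] < r[1] || p[["mean"]] > r[2]) {
      stop(what, sprintf(": truncation range [%g, %g] does not contain the mean %g",
                         r[1], r[2], p[["mean"]]), call. = FALSE)
    }
  }
  for (key in per_sub) {
    for (cls in c("organic", "minerogenic")) {
      p <- get_ms(cfg[[key]][[cls]], paste(key, cls))
      cfg[[key]][[cls]] <- list(mean = p[["mean"]], sd = p[["sd"]])
      check_ms(p, key, paste(key, cls))
    }
  }
  for (key in shared) {
    p <- get_ms(cfg[[key]], key)
    cfg[[key]] <- list(mean = p[["mean"]], sd = p[["sd"]])
    check_ms(p, key, key)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("synthetic lichen-isotope generator configuration\n")
  cat(sprintf("  survey: %d organic + %d minerogenic specimens; %d separated populations\n",
              x$n_organic, x$n_minerogenic, x$n_populations))
  cat(sprintf("  noise %.2f permil, carbon %.1f wt%%, seed %d\n",
              x$measurement_noise_sd, x$carbon_wt_pct, x$seed))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' Round-trips every [generator_config()] field through a flat YAML file.
#'
#' @param path YAML file path.
#' @return `read_generator_config()` returns a validated `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$truncation_ranges <- lapply(raw$truncation_ranges, unlist)
  do.call(generator_config, raw)
}

#' @rdname read_generator_config
#' @param config A `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  out <- unclass(config)
  out$truncation_ranges <- lapply(out$truncation_ranges, as.numeric)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Draw per-unit biont and composition values for one substrate class.
draw_class <- function(cfg, class, n, id_prefix) {
  r <- cfg$truncation_ranges
  draw <- function(param, range_key) {
    rtruncnorm(n, param$mean, param$sd, r[[range_key]][1], r[[range_key]][2])
  }
  d15N_P <- draw(cfg$photobiont_d15N[[class]], "photobiont_d15N")
  d15N_M <- draw(cfg$mycobiont_d15N[[class]], "mycobiont_d15N")
  d13C_P <- draw(cfg$photobiont_d13C, "photobiont_d13C")
  d13C_M <- draw(cfg$mycobiont_d13C, "mycobiont_d13C")
  CN_P <- draw(cfg$photobiont_CN, "photobiont_CN")
  CN_M <- draw(cfg$mycobiont_CN, "mycobiont_CN")
  f_true <- draw(cfg$f_M_B[[class]], "f_M_B")
  N_P <- cfg$carbon_wt_pct / CN_P
  N_M <- cfg$carbon_wt_pct / CN_M

  f_M_N <- f_true * N_M / (f_true * N_M + (1 - f_true) * N_P)
  d15N_L <- f_M_N * d15N_M + (1 - f_M_N) * d15N_P +
    stats::rnorm(n, 0, cfg$measurement_noise_sd)
  # whole-lichen delta13C: carbon-mass-weighted linear mix (equal carbon
  # content, so weights are the biomass fractions) plus the survey-level
  # substrate offset; emulation only, not part of the nitrogen model
  shift <- if (class == "minerogenic") cfg$d13C_substrate_shift else 0
  d13C_L <- f_true * d13C_M + (1 - f_true) * d13C_P + shift +
    stats::rnorm(n, 0, cfg$measurement_noise_sd)
  N_L <- f_true * N_M + (1 - f_true) * N_P

  tibble::tibble(
    unit_id = sprintf("%s_%s_%02d", id_prefix, substr(class, 1, 3), seq_len(n)),
    substrate_class = class,
    d15N_P = d15N_P, d15N_M = d15N_M, d13C_P = d13C_P, d13C_M = d13C_M,
    CN_P = CN_P, CN_M = CN_M, N_P = N_P, N_M = N_M,
    f_true = f_true, d15N_L = d15N_L, d13C_L = d13C_L, N_L = N_L
  )
}

#' Generate matched whole-lichen and biont measurements with known truth
#'
#' Emulates the biont-separation design: for each population, biont
#' delta15N, delta13C and C/N values are drawn from truncated normals, a
#' true mycobiont biomass fraction is drawn, and the whole-lichen delta15N
#' is built with the forward concentration-dependent mixing model plus
#' measurement noise. The generating biomass fractions are returned in a
#' separate truth table so recovery can be scored.
#'
#' @param config A [generator_config()].
#' @return A list with `specimens` (tidy specimen tibble, three rows per
#'   population), `triplets` (the matched wide table from
#'   [group_triplets()]) and `truth` (tibble: `population_id`,
#'   `substrate_class`, `true_f_M_B`).
#' @export
generate_triplets <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_org <- ceiling(config$n_populations / 2)
  n_min <- config$n_populations - n_org
  units <- withr::with_seed(config$seed, {
    dplyr::bind_rows(
      draw_class(config, "organic", n_org, "pop"),
      draw_class(config, "minerogenic", n_min, "pop")
    )
  })
  if (nrow(units) == 0) stop("n_populations must be >= 1", call. = FALSE)
  C <- config$carbon_wt_pct
  specimens <- dplyr::bind_rows(
    tibble::tibble(
      specimen_id = paste0(units$unit_id, "_L"), population_id = units$unit_id,
      site = "synthetic", substrate_class = units$substrate_class,
      tissue = "whole_lichen", d15N = units$d15N_L, d13C = units$d13C_L,
      N_wt_pct = units$N_L, C_wt_pct = C, CN_ratio = C / units$N_L
    ),
    tibble::tibble(
      specimen_id = paste0(units$unit_id, "_P"), population_id = units$unit_id,
      site = "synthetic", substrate_class = units$substrate_class,
      tissue = "photobiont", d15N = units$d15N_P, d13C = units$d13C_P,
      N_wt_pct = units$N_P, C_wt_pct = C, CN_ratio = units$CN_P
    ),
    tibble::tibble(
      specimen_id = paste0(units$unit_id, "_M"), population_id = units$unit_id,
      site = "synthetic", substrate_class = units$substrate_class,
      tissue = "mycobiont", d15N = units$d15N_M, d13C = units$d13C_M,
      N_wt_pct = units$N_M, C_wt_pct = C, CN_ratio = units$CN_M
    )
  )
  specimens <- specimens[order(specimens$population_id, specimens$tissue), ]
  # the wide triplet table is assembled directly (identical to what
  # group_triplets() recovers from the long table, but without the per-
  # population pairing pass, so very large simulated designs stay fast)
  triplets <- tibble::tibble(
    population_id = units$unit_id,
    substrate_class = units$substrate_class,
    site = "synthetic",
    d15N_L = units$d15N_L, d13C_L = units$d13C_L,
    N_L = units$N_L, CN_L = C / units$N_L,
    d15N_P = units$d15N_P, d13C_P = units$d13C_P,
    N_P = units$N_P, CN_P = units$CN_P,
    d15N_M = units$d15N_M, d13C_M = units$d13C_M,
    N_M = units$N_M, CN_M = units$CN_M
  )
  triplets <- triplets[order(triplets$population_id), ]
  attr(triplets, "excluded") <- tibble::tibble(population_id = character(),
                                               reason = character())
  list(
    specimens = validate_specimens(specimens),
    triplets = triplets,
    truth = tibble::tibble(
      population_id = units$unit_id,
      substrate_class = units$substrate_class,
      true_f_M_B = units$f_true
    )
  )
}

#' Generate a whole-lichen survey
#'
#' Emulates the field survey: each specimen receives its own latent biont
#' values and biomass fraction, and only the whole-lichen measurement is
#' reported. The per-substrate delta15N distributions are therefore
#' composition-driven - the substrate contrast emerges from the biont
#' parameter differences and biomass fractions rather than from a configured
#' shift.
#'
#' @param config A [generator_config()] with `n_organic >= 1` and
#'   `n_minerogenic >= 1`.
#' @return A tidy specimen tibble of `whole_lichen` records.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_organic < 1 || config$n_minerogenic < 1) {
    stop("survey generation requires n_organic >= 1 and n_minerogenic >= 1 (both classes are needed downstream)",
         call. = FALSE)
  }
  units <- withr::with_seed(config$seed, {
    dplyr::bind_rows(
      draw_class(config, "organic", config$n_organic, "survey"),
      draw_class(config, "minerogenic", config$n_minerogenic, "survey")
    )
  })
  C <- config$carbon_wt_pct
  validate_specimens(tibble::tibble(
    specimen_id = units$unit_id,
    population_id = units$unit_id,
    site = "synthetic",
    substrate_class = units$substrate_class,
    tissue = "whole_lichen",
    d15N = units$d15N_L, d13C = units$d13C_L,
    N_wt_pct = units$N_L, C_wt_pct = C, CN_ratio = C / units$N_L
  ))
}
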