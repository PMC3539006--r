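# Shared fixtures: small specimen tables and an independent Mann-Whitney
# oracle used to cross-check the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_specimens <- function() {
  tibble::tibble(
    specimen_id = c("s1", "s1p", "s1m", "s2", "s2p", "s2m"),
    population_id = rep(c("popA", "popB"), each = 3),
    site = "siteX",
    substrate_class = rep(c("organic", "minerogenic"), each = 3),
    tissue = rep(c("whole_lichen", "photobiont", "mycobiont"), 2),
    d15N = c(-9.5, -15.8, -7.7, -6.1, -15.7, -4.2),
    d13C = c(-24.0, -25.4, -22.0, -21.5, -25.2, -21.8),
    N_wt_pct = c(1.0, 3.5, 0.8, 0.9, 3.4, 0.85),
    C_wt_pct = c(45, 45, 45, 45, 45, 45),
    CN_ratio = NA_real_
  )
}

# n complete populations, three tissues each, deterministic values
make_population_records <- function(n_pops) {
  dplyr::bind_rows(lapply(seq_len(n_pops), function(i) {
    tibble::tibble(
      specimen_id = paste0("p", i, c("L", "P", "M")),
      population_id = paste0("pop", i),
      site = "siteX",
      substrate_class = if (i %% 2 == 0) "minerogenic" else "organic",
      tissue = c("whole_lichen", "photobiont", "mycobiont"),
      d15N = c(-8 - 0.1 * i, -16 + 0.05 * i, -5 - 0.2 * i),
      d13C = c(-23, -25.4, -22),
      N_wt_pct = c(1.1, 3.5, 0.8),
      C_wt_pct = 45,
      CN_ratio = NA_real_
    )
  }))
}

# Independent Mann-Whitney oracle: U by direct pairwise comparison (not
# ranks) and the exact two-sided p by enumerating every labeling.
oracle_mann_whitney <- function(A, B) {
  pooled <- c(A, B)
  n_A <- length(A)
  n <- length(pooled)
  u_of <- function(a_idx) {
    a <- pooled[a_idx]
    b <- pooled[setdiff(seq_len(n), a_idx)]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_of(seq_len(n_A))
  us <- apply(utils::combn(n, n_A), 2, u_of)
  mu <- n_A * length(B) / 2
  list(U = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-9))
}

random_end_members <- function(rng_n = 1) {
  d15N_P <- stats::runif(1, -22, -10)
  d15N_M <- d15N_P + sample(c(-1, 1), 1) * stats::runif(1, 1, 15)
  N_M <- stats::runif(1, 0.5, 4)
  end_members(d15N_M, d15N_P, N_M, N_P = N_M * stats::runif(1, 1 / 8, 8))
}
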