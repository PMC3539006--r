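test_that("U statistic and exact p match hand-enumerated examples", {
  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_two_sided, 2 / 6)
  expect_equal(sep$method, "exact_enumeration")

  degen <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(degen$U, 4.5)
  expect_equal(degen$p_two_sided, 1)

  ident <- mann_whitney_u(c(5, 5), c(5, 5, 5))
  expect_true(ident$degenerate)
  expect_equal(ident$p_two_sided, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "at least one")
})

test_that("exact test agrees with independent enumeration for small samples", {
  set.seed(11)
  for (rep in 1:40) {
    n_A <- sample(1:6, 1)
    n_B <- sample(1:(10 - n_A), 1)
    with_ties <- rep %% 2 == 0
    A <- if (with_ties) sample(1:4, n_A, replace = TRUE) else stats::rnorm(n_A)
    B <- if (with_ties) sample(1:4, n_B, replace = TRUE) else stats::rnorm(n_B)
    got <- mann_whitney_u(A, B)
    want <- oracle_mann_whitney(A, B)
    expect_equal(got$U, want$U)
    expect_equal(got$p_two_sided, want$p)
    if (!with_ties) {
      # independent reference implementation, tie-free exact case
      expect_equal(got$p_two_sided,
                   stats::wilcox.test(A, B, exact = TRUE)$p.value)
    }
  }
})

test_that("U statistics of the two groups always sum to n_A * n_B", {
  set.seed(13)
  for (rep in 1:50) {
    A <- sample(1:6, sample(2:12, 1), replace = TRUE)
    B <- sample(1:6, sample(2:12, 1), replace = TRUE)
    expect_equal(mann_whitney_u(A, B)$U + mann_whitney_u(B, A)$U,
                 length(A) * length(B))
  }
})

test_that("normal approximation tracks a permutation reference at moderate n", {
  set.seed(17)
  A <- stats::rnorm(20, 0.3)
  B <- stats::rnorm(20)
  approx_p <- mann_whitney_u(A, B, method = "normal")$p_two_sided
  # Monte-Carlo permutation reference for the same symmetric-deviation p
  pooled <- c(A, B)
  ranks <- rank(pooled)
  mu <- 20 * 20 / 2
  u_obs <- sum(ranks[1:20]) - 20 * 21 / 2
  perm <- replicate(40000, {
    idx <- sample(40, 20)
    sum(ranks[idx]) - 20 * 21 / 2
  })
  mc_p <- mean(abs(perm - mu) >= abs(u_obs - mu) - 1e-9)
  expect_lt(abs(approx_p - mc_p), 0.01)
})

test_that("substrate contrast reports minerogenic-minus-organic differences", {
  cfg <- generator_config(seed = 19)
  sv <- generate_survey(cfg)
  cmp <- substrate_contrast(sv, "d15N")
  expect_equal(cmp$n_A + cmp$n_B, 82)
  # composition-driven enrichment on minerogenic substrate
  expect_gt(cmp$mean_difference, 2)
  expect_lt(cmp$mean_difference, 5.5)
  expect_lt(cmp$p_two_sided, 0.01)

  c13 <- substrate_contrast(sv, "d13C")
  expect_lt(abs(c13$mean_difference - 2.6), 3 * 0.6)  # configured shift, ~3 SE
  expect_lt(c13$p_two_sided, 0.01)

  same <- make_specimens()
  same$substrate_class <- rep(c("organic", "minerogenic"), 3)
  same$tissue <- "whole_lichen"
  same$d15N <- rep(c(-9, -9, -9), 2)
  cmp0 <- substrate_contrast(same, "d15N")
  expect_equal(cmp0$mean_difference, 0)
  expect_equal(cmp0$p_two_sided, 1)

  one_class <- sv[sv$substrate_class == "organic", ]
  expect_error(substrate_contrast(one_class, "d15N"), "both substrate classes")
})

test_that("grouped summaries use sample SD and report printed-style ranges", {
  recs <- make_specimens()
  s <- grouped_summary(recs, "d15N", group_by = "tissue")
  phot <- s[s$group == "photobiont", ]
  expect_equal(phot$n, 2)
  expect_equal(phot$mean, mean(c(-15.8, -15.7)))
  expect_equal(phot$sd, stats::sd(c(-15.8, -15.7)))
  expect_equal(c(phot$min, phot$max), c(-15.8, -15.7))

  single <- recs[1, ]
  s1 <- grouped_summary(single, "d15N", group_by = "substrate_class")
  expect_true(is.na(s1$sd))
  expect_error(grouped_summary(recs, "d15N", group_by = "site"))
})

test_that("biont correlation flags collinear d13C and independent d15N", {
  trip <- group_triplets(make_population_records(8))
  trip$d13C_P <- -28 + 0.5 * seq_len(8)
  trip$d13C_M <- -24 + 0.25 * seq_len(8)  # perfectly collinear
  rep_ <- biont_correlation(trip)
  expect_equal(rep_$r[rep_$isotope == "d13C"], 1)
  expect_true(rep_$significant[rep_$isotope == "d13C"])

  trip$d13C_M <- -20 - 0.25 * seq_len(8)  # anti-collinear
  expect_equal(biont_correlation(trip)$r[2], -1)

  trip$d15N_P <- rep(-15.8, 8)  # zero variance
  rep0 <- biont_correlation(trip)
  expect_true(rep0$degenerate[rep0$isotope == "d15N"])
  expect_error(biont_correlation(trip[1:2, ]), "at least 3")
})

test_that("independent biont d15N values rarely appear correlated", {
  set.seed(23)
  false_pos <- 0
  for (i in 1:500) {
    trip <- tibble::tibble(
      population_id = as.character(1:10),
      d15N_P = stats::rnorm(10, -15.8, 2.6),
      d15N_M = stats::rnorm(10, -7.7, 1.9),
      d13C_P = stats::rnorm(10, -25.4, 1.7),
      d13C_M = stats::rnorm(10, -22, 1.1)
    )
    r <- biont_correlation(trip)
    if (isTRUE(r$significant[r$isotope == "d15N"])) false_pos <- false_pos + 1
  }
  expect_lt(false_pos / 500, 0.10)
})
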