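# Reliability and group-comparison statistics: Cronbach's alpha against an
# ANOVA ICC(3,k) oracle, Feldt interval behaviour, t-test and chi-square
# contracts, group summaries, and literature pooling against a raw-data
# concatenation oracle.

test_that("alpha is 1 for identical and for congeneric rater columns", {
  m <- matrix(rep(c(3, 7, 1, 9), 3), ncol = 3)
  expect_equal(cronbach_alpha(m)$alpha, 1, tolerance = 1e-12)
  cong <- cbind(1:4, 2:5, 3:6)
  res <- cronbach_alpha(cong)
  expect_equal(res$alpha, 1, tolerance = 1e-12)
  expect_equal(res$alpha, oracle_icc3k(cong), tolerance = 1e-12)
})

test_that("alpha equals the ANOVA ICC(3,k) oracle on seeded matrices", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    k <- sample(2:5, 1)
    truth <- stats::rnorm(n, 25, 20)
    m <- sapply(seq_len(k), function(j) {
      truth * stats::runif(1, 0.8, 1.2) + stats::rnorm(n, 0, 5) +
        stats::rnorm(1, 0, 3)
    })
    a <- cronbach_alpha(m)
    expect_equal(a$alpha, oracle_icc3k(m), tolerance = 1e-12)
    expect_lte(a$alpha, 1)
    expect_lte(a$ci_low, a$alpha)
    expect_gte(a$ci_high, a$alpha)
  }
})

test_that("alpha of independent noise is near zero and never above one", {
  set.seed(33)
  m <- matrix(stats::rnorm(200 * 3), ncol = 3)
  a <- cronbach_alpha(m)
  expect_lt(abs(a$alpha), 0.25)
  expect_lte(a$alpha, 1)
})

test_that("alpha is invariant to shifting or scaling all ratings", {
  set.seed(44)
  m <- sapply(1:3, function(j) stats::rnorm(12, 30, 10) + j)
  base <- cronbach_alpha(m)$alpha
  expect_equal(cronbach_alpha(m + 100)$alpha, base, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m * 3.7)$alpha, base, tolerance = 1e-12)
})

test_that("alpha input contracts: completeness, size, variance", {
  expect_error(cronbach_alpha(matrix(c(1, 2, NA, 4), 2)),
               class = "circlehta_error_input")
  expect_error(cronbach_alpha(matrix(1:3, 3, 1)),
               class = "circlehta_error_input")
  expect_error(cronbach_alpha(matrix(5, 4, 3)),
               class = "circlehta_error_degenerate")
})

test_that("ratings_matrix pivots long records and enforces completeness", {
  long <- tidyr::expand_grid(case_id = sprintf("c%d", 1:4),
                             rater_id = c("r1", "r2", "r3"))
  long$quantity <- "hta_circle"
  long$value_deg <- seq_len(nrow(long)) * 1.5
  m <- ratings_matrix(long, "hta_circle")
  expect_equal(dim(m), c(4, 3))
  expect_error(ratings_matrix(long[-1, ], "hta_circle"),
               class = "circlehta_error_input")
  expect_error(ratings_matrix(dplyr::bind_rows(long, long[1, ]), "hta_circle"),
               class = "circlehta_error_input")
})

test_that("t-test behaviour on equal, shifted-constant and regular samples", {
  x <- c(5, 7, 9, 11)
  # x vs itself paired: constant zero differences -> degenerate
  expect_error(hta_t_test(x, x, paired = TRUE),
               class = "circlehta_error_degenerate")
  # constant non-zero differences likewise undefined
  expect_error(hta_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5), paired = TRUE),
               class = "circlehta_error_degenerate")
  set.seed(55)
  a <- stats::rnorm(30); b <- stats::rnorm(30, 0.5)
  welch <- hta_t_test(a, b)
  expect_equal(welch$p_value,
               stats::t.test(a, b)$p.value, tolerance = 1e-12)
  student <- hta_t_test(a, b, var_equal = TRUE)
  expect_equal(student$df, 58)
  paired <- hta_t_test(a, b, paired = TRUE)
  expect_equal(paired$p_value, stats::t.test(a - b)$p.value, tolerance = 1e-12)
})

test_that("Welch p agrees with a permutation oracle on a seeded fixture", {
  set.seed(66)
  x <- stats::rnorm(30, 25, 10)
  y <- stats::rnorm(30, 35, 10)
  p_w <- hta_t_test(x, y)$p_value
  set.seed(67)
  p_perm <- oracle_perm_p(x, y, n_perm = 2e4)
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  expect_lt(abs(p_w - p_perm), 4 * se + 0.005)
})

test_that("chi-square 2x2 matches closed forms and the printed gender table", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  diag40 <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag40$statistic, 40)
  gender <- chi_square_2x2(matrix(c(10, 10, 22, 25), 2))
  expect_equal(gender$p_value, 0.81085, tolerance = 1e-4)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "circlehta_error_input")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)),
               class = "circlehta_error_input")
})

test_that("group summaries report n, mean, range and (n-1) SD", {
  one <- group_summary(25, "single")
  expect_equal(one$n, 1)
  expect_equal(one$sd_deg, 0)
  expect_false(one$sd_defined)
  two <- group_summary(c(-73, 83), "range")
  expect_equal(two$min_deg, -73)
  expect_equal(two$max_deg, 83)
  expect_equal(two$mean_deg, 5)
  set.seed(77)
  v <- stats::rnorm(40, 25, 25)
  g <- group_summary(v, "cohort")
  expect_equal(g$mean_deg, sum(v) / 40, tolerance = 1e-12)
  expect_equal(g$sd_deg, sqrt(sum((v - mean(v))^2) / 39), tolerance = 1e-12)
  expect_error(group_summary(numeric(0)), class = "circlehta_error_input")
})

test_that("summarise_results splits by method and grouping column", {
  res <- dplyr::bind_rows(lapply(1:6, function(i) {
    grp <- if (i <= 3) "stable" else "unstable"
    ph <- generate_case(phantom_spec(theta_true = 10 * i, sigma_contour = 0),
                        seed = i)
    out <- measure_case(ph$case)
    out$group <- grp
    out
  }))
  tab <- summarise_results(res, by = "group")
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$n, c(3, 3, 3, 3))
  stable_circle <- dplyr::filter(tab, method == "circle", group == "stable")
  expect_equal(stable_circle$mean_deg, 20, tolerance = 1e-6)
})

test_that("pooling matches the raw-data concatenation oracle and is convex", {
  single <- pool_studies(tibble::tibble(study = "a", modality = "ct",
                                        n = 10, mean_deg = 20, sd_deg = 5))
  expect_equal(single$n_total, 10)
  expect_equal(single$mean_deg, 20)
  expect_equal(single$sd_deg, 5)

  set.seed(88)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    rec <- tibble::tibble(
      study = sprintf("s%d", seq_len(k)), modality = "ct",
      n = sample(2:200, k, replace = TRUE),
      mean_deg = stats::runif(k, -20, 70),
      sd_deg = stats::runif(k, 0.5, 20))
    pooled <- pool_studies(rec)
    oracle <- oracle_pool_raw(rec)
    expect_equal(pooled$n_total, oracle$n_total)
    expect_equal(pooled$mean_deg, oracle$mean, tolerance = 1e-12)
    expect_equal(pooled$sd_deg, oracle$sd, tolerance = 1e-12)
    expect_gte(pooled$mean_deg, min(rec$mean_deg))
    expect_lte(pooled$mean_deg, max(rec$mean_deg))
  }

  # a record without SD suppresses the pooled SD but not the mean
  rec <- tibble::tibble(study = c("a", "b"), modality = "ct",
                        n = c(4, 6), mean_deg = c(10, 20),
                        sd_deg = c(2, NA))
  pooled <- pool_studies(rec)
  expect_equal(pooled$mean_deg, 16)
  expect_true(is.na(pooled$sd_deg))
  expect_error(pool_studies(rec, modality = "ultrasound"),
               class = "circlehta_error_input")
})
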