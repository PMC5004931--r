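test_that("cohort summaries use per-column complete cases and sample SD", {
  tab <- data.frame(case_id = letters[1:5],
                    a = c(1, 2, 3, NA, NA),
                    b = c(5, 5, 5, 5, 5),
                    c = rep(NA_real_, 5), check.names = FALSE)
  s <- summarize_cohort(tab)
  ra <- s[s$Measurement == "a", ]
  expect_equal(ra$N, 3); expect_equal(ra$Mean, 2)
  expect_equal(ra[["Std Dev"]], 1)
  expect_equal(ra$Minimum, 1); expect_equal(ra$Maximum, 3)
  expect_equal(s[s$Measurement == "b", "Std Dev"], 0)
  expect_equal(s[s$Measurement == "c", "N"], 0)
  expect_true(is.na(s[s$Measurement == "c", "Mean"]))
})

test_that("pearson_matrix: exact, sampled and degenerate correlations", {
  x <- 1:10
  tab <- data.frame(x = x, y = 2 * x, z = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  rep <- pearson_matrix(tab)
  expect_equal(rep$r["x", "y"], 1)
  expect_lte(rep$p["x", "y"], 1e-12)
  expect_equal(diag(rep$r), c(x = 1, y = 1, z = 1))
  expect_equal(rep$r, t(rep$r))
  expect_true(all(abs(rep$r) <= 1))

  # sampled bivariate normal, rho = 0.8, n = 500: the estimate must land in
  # the Fisher-z 99% interval (0.7547, 0.8380), frozen from the closed form
  set.seed(7)
  xy <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, 0.8, 0.8, 1), 2))
  rep2 <- pearson_matrix(data.frame(u = xy[, 1], v = xy[, 2]))
  expect_gt(rep2$r["u", "v"], 0.7547)
  expect_lt(rep2$r["u", "v"], 0.8380)

  # constant column: undefined and flagged
  expect_warning(rep3 <- pearson_matrix(data.frame(x = x, k = rep(2, 10))),
                 "constant")
  expect_true(is.na(rep3$r["x", "k"]))

  # pairwise-complete counts never exceed column Ns
  tab$y[1:4] <- NA
  rep4 <- pearson_matrix(tab)
  expect_equal(rep4$n["x", "y"], 6)
  expect_error(pearson_matrix(data.frame(x = 1:3)), "two numeric")
})

test_that("P values shrink as |r| grows at fixed n", {
  # engineer exact sample correlations: unit-norm centred x and an
  # orthogonal unit-norm z give cor(x, rho*x + sqrt(1-rho^2)*z) = rho
  set.seed(12)
  n <- 30
  x <- scale(rnorm(n))[, 1]; x <- x / sqrt(sum(x^2))
  z <- rnorm(n); z <- z - mean(z) - x * sum(x * (z - mean(z)))
  z <- z / sqrt(sum(z^2))
  ps <- vapply(c(0.2, 0.5, 0.8, 0.95), function(rho) {
    y <- rho * x + sqrt(1 - rho^2) * z
    pearson_matrix(data.frame(a = x, b = y))$p["a", "b"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("interpretation bands partition [0,1] with upper-inclusive ties", {
  expect_equal(interpret_r(0.95), "very high")
  expect_equal(interpret_r(0.85), "high")
  expect_equal(interpret_r(0.60), "moderate")
  expect_equal(interpret_r(0.40), "low")
  expect_equal(interpret_r(0.10), "negligible")
  # boundaries belong to the upper band
  expect_equal(interpret_r(c(0.90, 0.70, 0.50, 0.30)),
               c("very high", "high", "moderate", "low"))
  expect_equal(interpret_r(-0.45), "low")  # band is on |r|
  expect_equal(interpret_r(1), "very high")
  # every |r| maps to exactly one band
  rs <- seq(0, 1, by = 0.001)
  expect_true(all(interpret_r(rs) %in%
                    c("negligible", "low", "moderate", "high", "very high")))
  expect_error(interpret_r(1.01), "<= 1")
})

test_that("clustering on 1 - r groups correlated variables", {
  set.seed(3)
  n <- 400
  a <- rnorm(n)
  b <- 0.95 * a + sqrt(1 - 0.95^2) * rnorm(n)
  c <- rnorm(n)
  rep <- pearson_matrix(data.frame(A = a, B = b, C = c))
  cl <- cluster_variables(rep)
  posA <- match("A", cl$labels); posB <- match("B", cl$labels)
  expect_equal(abs(posA - posB), 1)  # forced first merge => adjacent leaves

  # identical duplicated column: distance 0, merged first
  rep2 <- pearson_matrix(data.frame(A = a, A2 = a, C = c))
  cl2 <- cluster_variables(rep2)
  first <- sort(-cl2$tree$merge[1, ])
  expect_equal(cl2$tree$labels[first], c("A", "A2"))
  expect_equal(cl2$tree$height[1], 0)

  # independent columns: tree still valid with all leaves
  rep3 <- pearson_matrix(as.data.frame(matrix(rnorm(200 * 5), 200)))
  cl3 <- cluster_variables(rep3)
  expect_setequal(cl3$labels, rep3$variables)

  rep_const <- suppressWarnings(pearson_matrix(
    data.frame(A = a, B = b, K = c(rep(1, n)))))
  expect_warning(cluster_variables(rep_const), "imputed")
})

test_that("cortex/medulla ranking is ordered, banded and tolerant of gaps", {
  sc <- simulate_cohort(cohort_spec(n_cases = 4000, missingness = 0, seed = 11))
  rep <- pearson_matrix(sc$table)
  pairs <- compartment_pairs()
  rk <- rank_compartment_correlations(rep, pairs)
  expect_true(all(diff(rk$r) <= 0))
  expect_true(all(rk$group[rk$band %in% c("high", "very high")] == "Highly correlated"))
  # measures with well-separated targets keep their true order
  expect_lt(match("Tri", rk$measure), match("Vis-Tri", rk$measure))  # 0.68 vs 0.60
  expect_lt(match("PAS", rk$measure), match("MVA", rk$measure))      # 0.87 vs 0.71

  # single pair
  one <- rank_compartment_correlations(rep, pairs[1, , drop = FALSE])
  expect_equal(nrow(one), 1)
  # missing member skipped with warning
  pairs2 <- rbind(pairs[1:2, ],
                  data.frame(measure = "ghost", var1 = "nope", var2 = "Med-Tri"))
  expect_warning(rk2 <- rank_compartment_correlations(rep, pairs2), "skipped")
  expect_equal(nrow(rk2), 2)
})

test_that("long format mirrors the matrices", {
  tab <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  rep <- pearson_matrix(tab)
  lg <- correlation_long(rep)
  expect_equal(nrow(lg), 3)
  i <- which(lg$var1 == "a" & lg$var2 == "c")
  expect_equal(lg$r[i], rep$r["a", "c"])
  expect_equal(lg$band[i], interpret_r(rep$r["a", "c"]))
})
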