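test_that("min-max normalization maps endpoints and handles constant columns", {
  X <- cbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(1, 4, 2))
  expect_warning(nm <- normalize_minmax(X), "constant")
  expect_equal(nm$Z[, "a"], c(0, 0.5, 1))
  expect_equal(nm$Z[, "b"], c(0.5, 0.5, 0.5))
  expect_true(all(nm$Z >= 0 & nm$Z <= 1))

  set.seed(1)
  Y <- matrix(rexp(15), 5, 3)
  Z <- normalize_minmax(Y)$Z
  # element-wise two-pass re-computation
  for (j in 1:3) for (i in 1:5) {
    expect_equal(Z[i, j], (Y[i, j] - min(Y[, j])) / (max(Y[, j]) - min(Y[, j])))
  }
})

test_that("relational coefficients match the formula bounds and extremes", {
  set.seed(2)
  Z <- matrix(runif(24), 8, 3)
  Z[1, ] <- 1                       # a sample identical to the reference
  Z[2, 1] <- 0                      # force the global max deviation to 1
  gam <- relational_coefficients(Z, rho = 0.5)
  expect_equal(dim(gam), c(3, 8))
  expect_true(all(gam >= 0.5 / 1.5 - 1e-12 & gam <= 1 + 1e-12))
  expect_equal(unname(gam[, 1]), rep(1, 3))         # zero deviation row
  expect_equal(gam[1, 2], 1 / 3)                    # rho/(1+rho) at max deviation
  expect_error(relational_coefficients(Z, rho = 0), "rho")
  expect_error(relational_coefficients(Z, rho = 1), "rho")
})

test_that("indicator weights normalize relational degrees", {
  gam_same <- matrix(0.7, 4, 10)
  expect_equal(unname(indicator_weights(gam_same)), rep(0.25, 4))
  gam <- rbind(c(1, 1), c(0.5, 0.5))
  expect_equal(unname(indicator_weights(gam)), c(2 / 3, 1 / 3))
  set.seed(3)
  G <- matrix(runif(300, 0.3, 1), 6, 50)
  w <- indicator_weights(G)
  # independent double-loop summation
  tot <- 0; rs <- numeric(6)
  for (i in 1:6) for (k in 1:50) { tot <- tot + G[i, k]; rs[i] <- rs[i] + G[i, k] }
  expect_equal(unname(w), rs / tot, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("composite risk is the weighted profile, bounded in [0, 1]", {
  w <- c(0.2, 0.3, 0.5)
  expect_equal(composite_risk(matrix(1, 4, 3), w), rep(1, 4))
  expect_equal(composite_risk(matrix(0, 4, 3), w), rep(0, 4))
  set.seed(4)
  Z <- matrix(runif(30), 10, 3)
  r <- composite_risk(Z, w)
  for (k in 1:10) expect_equal(r[k], sum(w * Z[k, ]), tolerance = 1e-12)
  expect_error(composite_risk(Z, c(0.5, 0.5)), "mismatch")
})

test_that("full GRA pipeline matches the loop-based oracle on random tables", {
  for (s in 1:20) {
    tab <- random_table(8, seed = 100 + s)
    sc <- gra_score(tab, rho = 0.5)
    orc <- gra_oracle(indicator_matrix(tab), rho = 0.5)
    expect_equal(unname(sc$weights), orc$weights, tolerance = 1e-10)
    expect_equal(sc$risk, orc$risk, tolerance = 1e-10)
    expect_equal(unname(sc$coefficients), unname(orc$gamma), tolerance = 1e-10)
  }
})

test_that("GRA result invariants hold across many random tables", {
  for (s in 1:60) {
    tab <- random_table(sample(4:12, 1), seed = 500 + s)
    sc <- gra_score(tab, rho = 0.5)
    expect_true(all(sc$coefficients >= 0.5 / 1.5 - 1e-12 &
                      sc$coefficients <= 1 + 1e-12))
    expect_equal(sum(sc$weights), 1, tolerance = 1e-9)
    expect_true(all(sc$weights >= 0))
    expect_true(all(sc$risk >= -1e-12 & sc$risk <= 1 + 1e-12))
  }
})

test_that("scores are invariant to positive per-column rescaling", {
  tab <- random_table(15, seed = 77)
  sc1 <- gra_score(tab)
  X <- indicator_matrix(tab)
  scale <- c(1000, 0.01, 7, 3.2, 1e-4, 42)
  X2 <- sweep(X, 2, scale, "*")
  df <- as.data.frame(tab)
  df[, colnames(X2)] <- X2
  sc2 <- gra_score(as_contaminant_table(df, attr(tab, "indicators")))
  expect_equal(sc1$weights, sc2$weights, tolerance = 1e-10)
  expect_equal(sc1$risk, sc2$risk, tolerance = 1e-10)
})

test_that("row permutation permutes risks and keeps weights", {
  tab <- random_table(12, seed = 88)
  sc1 <- gra_score(tab)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 4, 10, 6, 9, 7)
  df <- as.data.frame(tab)[perm, ]
  sc2 <- gra_score(as_contaminant_table(df, attr(tab, "indicators")))
  expect_equal(sc1$weights, sc2$weights, tolerance = 1e-12)
  expect_equal(sc2$risk, sc1$risk[perm], tolerance = 1e-12)
})

test_that("a dominant high-deviation indicator receives the largest weight", {
  # three indicators: one hugging the reference (small deviations, hence high
  # coefficients), two spread far away; the close-tracking indicator should
  # dominate the weights, and the ranking must match the oracle's
  set.seed(9)
  n <- 40
  X <- cbind(close = runif(n, 0.9, 1.0),
             far = runif(n, 0.0, 0.2),
             mid = runif(n, 0.4, 0.6))
  ind <- default_indicators()[1:3, ]; ind$name <- colnames(X)
  df <- data.frame(sample_id = sprintf("S%02d", 1:n), batch_id = "B1",
                   region = "R1", detection_date = as.Date("2020-01-01"),
                   stringsAsFactors = FALSE)
  # normalize per column so that column ranges are comparable;
  # raw values already lie in [0,1] ranges by construction
  tab <- as_contaminant_table(cbind(df, as.data.frame(X)), ind)
  sc <- gra_score(tab)
  orc <- gra_oracle(indicator_matrix(tab))
  expect_equal(unname(which.max(sc$weights)), which.max(orc$weights))
  # duplicating a row must not change which indicator dominates
  df2 <- as.data.frame(tab)[c(1:n, 1), ]
  df2$sample_id[n + 1] <- "S99"
  sc2 <- gra_score(as_contaminant_table(df2, ind))
  expect_equal(unname(which.max(sc2$weights)), unname(which.max(sc$weights)))
})

test_that("score_dataset emits histogram and labelled table", {
  tab <- generate_samples(generator_config(n_samples = 250, seed = 21))
  sc <- gra_score(tab)
  expect_equal(sum(sc$histogram), 250)
  expect_named(sc$table, c(names(as.data.frame(tab)), "risk_value"),
               ignore.order = FALSE)
  expect_equal(sc$table$risk_value, sc$risk)
  h <- risk_histogram(sc)
  expect_equal(sum(h$count), 250)
})
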