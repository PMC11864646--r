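# Median-ratio fitting and differential-abundance classification.

test_that("pairwise median ratios follow the pairwise-complete median
           convention", {
  m <- make_ion_matrix(list(c(2, 1), c(4, 2), c(6, 3)))
  M <- pairwise_median_ratios(m)
  expect_equal(M["r1", "r2"], 2)
  expect_equal(M["r2", "r1"], 0.5)
  expect_equal(diag(M), c(r1 = 1, r2 = 1))

  # even count: mean of the two middle values
  M2 <- pairwise_median_ratios(make_ion_matrix(list(c(2, 1), c(8, 2))))
  expect_equal(M2["r1", "r2"], 3)

  # an ion observed in only one run is excluded from that pair's median
  M3 <- pairwise_median_ratios(make_ion_matrix(list(c(2, 1), c(8, NA))))
  expect_equal(M3["r1", "r2"], 2)

  # no shared ion: ratio undefined and flagged
  M4 <- pairwise_median_ratios(make_ion_matrix(list(c(2, NA), c(NA, 3))))
  expect_true(is.na(M4["r1", "r2"]))
  expect_equal(attr(M4, "undefined_pairs"), "r1/r2")

  expect_error(pairwise_median_ratios(matrix(numeric(0), 0, 2)),
               "zero ions")
})

test_that("antisymmetry M[r,s] * M[s,r] = 1 holds wherever defined", {
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rlnorm(4 * 6), 4, 6,
                dimnames = list(paste0("ion", 1:4), paste0("r", 1:6)))
    m[sample(length(m), 5)] <- NA
    M <- pairwise_median_ratios(m)
    prod <- M * t(M)
    expect_equal(prod[!is.na(prod)],
                 rep(1, sum(!is.na(prod))))
  }
})

test_that("abundance fitting solves the two-run closed form and matches a
           generic least-squares oracle", {
  M <- matrix(c(1, 0.5, 2, 1), 2, 2,
              dimnames = list(c("r1", "r2"), c("r1", "r2")))
  expect_equal(fit_protein_abundances(M, ion_total = 18),
               c(r1 = 12, r2 = 6))

  # single run: gauge-only problem
  M1 <- matrix(1, 1, 1, dimnames = list("r1", "r1"))
  expect_equal(fit_protein_abundances(M1, 7), c(r1 = 7))

  # consistent 3-run system has zero residual: fitted ratios exactly 6:3:1
  M3 <- diag(1, 3)
  dimnames(M3) <- list(paste0("r", 1:3), paste0("r", 1:3))
  M3[1, 2] <- 2; M3[2, 1] <- 1 / 2
  M3[2, 3] <- 3; M3[3, 2] <- 1 / 3
  M3[1, 3] <- 6; M3[3, 1] <- 1 / 6
  ab <- fit_protein_abundances(M3, ion_total = 100)
  expect_equal(ab / ab["r3"], c(r1 = 6, r2 = 3, r3 = 1))
  expect_equal(sum(ab), 100)
  expect_equal(ab, lsq_fit_oracle(M3, 100))

  # inconsistent systems agree with the independent least-squares oracle
  set.seed(6)
  for (rep in 1:10) {
    k <- 4
    M <- diag(1, k)
    dimnames(M) <- list(paste0("r", 1:k), paste0("r", 1:k))
    for (r in 1:(k - 1)) for (s in (r + 1):k) {
      M[r, s] <- rlnorm(1)
      M[s, r] <- 1 / M[r, s]
    }
    total <- runif(1, 10, 1000)
    expect_equal(fit_protein_abundances(M, total), lsq_fit_oracle(M, total))
  }
})

test_that("a disconnected run graph raises an error naming the components", {
  M <- diag(1, 4)
  dimnames(M) <- list(paste0("r", 1:4), paste0("r", 1:4))
  M[1, 2] <- 2; M[2, 1] <- 0.5
  M[3, 4] <- 3; M[4, 3] <- 1 / 3
  M[1, 3] <- M[3, 1] <- M[1, 4] <- M[4, 1] <- NA
  M[2, 3] <- M[3, 2] <- M[2, 4] <- M[4, 2] <- NA
  expect_error(fit_protein_abundances(M, 10),
               "disconnected.*\\{r1, r2\\}.*\\{r3, r4\\}")
})

test_that("scale equivariance: scaling one run's ions scales its fitted
           abundance before the rescaling gauge", {
  set.seed(7)
  m <- matrix(rlnorm(5 * 3, meanlog = 5), 5, 3,
              dimnames = list(paste0("ion", 1:5), paste0("r", 1:3)))
  c_scale <- 8
  m2 <- m
  m2[, 2] <- m2[, 2] * c_scale
  M <- pairwise_median_ratios(m)
  M2 <- pairwise_median_ratios(m2)
  expect_equal(M2[2, 1], c_scale * M[2, 1])
  expect_equal(M2[2, 3], c_scale * M[2, 3])
  ab <- fit_protein_abundances(M, sum(m))
  ab2 <- fit_protein_abundances(M2, sum(m2))
  # ratios between unscaled runs are preserved; run 2 gains factor c
  expect_equal(ab2[2] / ab2[1], c_scale * ab[2] / ab[1])
  expect_equal(ab2[3] / ab2[1], ab[3] / ab[1], ignore_attr = TRUE)
})

test_that("noise-free synthetic ion data is recovered exactly and the
           rescaling contract holds", {
  sim <- generate_ion_abundances(n_proteins = 6, n_runs = 5,
                                 ions_per_protein = 4, noise_sd_log2 = 0,
                                 missing_rate = 0, seed = 11)
  ab <- quantify_proteins(sim$ions)
  tf <- sim$truth$run_factors
  expect_equal(ab / ab[, 1], tf / tf[, 1], tolerance = 1e-12)
  totals <- tapply(sim$ions$abundance, sim$ions$protein_id, sum)
  expect_equal(rowSums(ab), as.vector(totals[rownames(ab)]),
               ignore_attr = TRUE)
})

test_that("differential tests match t.test, flag degenerate cases, and
           respect thresholds in classification", {
  ab <- rbind(
    flat  = c(10, 11, 9, 10, 10.5, 9.5, 10, 11),
    up2x  = c(10, 11, 9, 10, 20, 22, 18, 20),
    exact = c(8, 8, 8, 8, 16, 16, 16, 16)
  )
  colnames(ab) <- paste0("r", 1:8)
  groups <- setNames(rep(c("g1", "g2"), each = 4), colnames(ab))
  res <- differential_test(ab, groups)
  expect_s3_class(res, "cma_diff")

  expect_equal(res$log2_fold_change[res$protein_id == "exact"], 1)
  expect_true(res$degenerate[res$protein_id == "exact"])
  expect_true(is.na(res$p_value[res$protein_id == "exact"]))

  i <- res$protein_id == "up2x"
  ref <- t.test(log2(ab["up2x", 5:8]), log2(ab["up2x", 1:4]),
                var.equal = TRUE)
  expect_equal(res$p_value[i], ref$p.value)
  expect_equal(res$log2_fold_change[i],
               mean(log2(ab["up2x", 5:8])) - mean(log2(ab["up2x", 1:4])))

  # identical groups: fold change 0, p = 1
  same <- differential_test(rbind(p = rep(c(3, 5, 4, 6), 2)),
                            rep(c("g1", "g2"), each = 4))
  expect_equal(same$log2_fold_change, 0)
  expect_equal(same$p_value, 1)

  # zeros count as missing; too-small groups are skipped and logged
  ab0 <- rbind(p1 = c(0, 0, 0, 12, 9, 11, 10, 10))
  colnames(ab0) <- paste0("r", 1:8)
  res0 <- differential_test(ab0, groups)
  expect_equal(nrow(res0), 0L)
  expect_equal(attr(res0, "skipped"), "p1")

  expect_error(differential_test(ab, rep("g1", 8)), "two groups")
  expect_error(differential_test(ab[, 1:3],
                                 setNames(c("g1", "g1", "g2"),
                                          paste0("r", 1:3))),
               "at least 2 runs")

  # classification thresholds
  recs <- data.frame(protein_id = c("a", "b", "c", "d"),
                     log2_fold_change = c(1, 0.4, -1, 1),
                     p_value = c(0.01, 0.001, 0.04, 0.2))
  cls <- classify_hits(recs)
  expect_equal(cls$call, c("up", "ns", "down", "ns"))
  s <- summary(cls)
  expect_equal(s$n_identified, 4L)
  expect_equal(s$n_up, 1L)
  # the stricter legacy cut of 2 is available by flag
  cls2 <- classify_hits(recs, fc_threshold = 2)
  expect_equal(cls2$call, c("ns", "ns", "ns", "ns"))
})

test_that("type-I error of the differential test is nominal on null data", {
  set.seed(13)
  n <- 400
  ab <- matrix(2^rnorm(n * 8, mean = 10, sd = 0.5), nrow = n,
               dimnames = list(paste0("p", 1:n), paste0("r", 1:8)))
  res <- differential_test(ab, rep(c("g1", "g2"), each = 4))
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("classification recovers planted up/down counts when effects
           clear the thresholds", {
  set.seed(14)
  n <- 300
  truth <- rep(c("up", "down", "ns"), times = c(30, 40, 230))
  shift <- ifelse(truth == "up", 2, ifelse(truth == "down", -2, 0))
  ab <- 2^(matrix(rnorm(n * 8, mean = 10, sd = 0.2), nrow = n) +
             outer(shift, c(0, 0, 0, 0, 1, 1, 1, 1)))
  rownames(ab) <- paste0("p", 1:n)
  colnames(ab) <- paste0("r", 1:8)
  res <- classify_hits(differential_test(ab, rep(c("g1", "g2"), each = 4)))
  expect_equal(res$call, truth)
})
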