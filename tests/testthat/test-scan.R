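test_that("interaction fit matches the normal-equations oracle", {
  set.seed(101)
  for (n in c(10, 50, 400)) {
    for (rep in 1:10) {
      st <- simulate_triplet(n, beta = runif(4, -1, 1), noise_sd = 1)
      fit <- fit_triplet(st$tv)
      ora <- ols_oracle(st$tv$x_tf, st$tv$x_m, st$tv$y_target)
      expect_equal(unname(fit$beta), ora$beta, tolerance = 1e-8)
      expect_equal(fit$se3, ora$se3, tolerance = 1e-8)
      expect_equal(fit$p3, ora$p3, tolerance = 1e-8)
    }
  }
})

test_that("noise-free data are interpolated exactly; degenerate designs flagged unfit", {
  st <- simulate_triplet(50, beta = c(2, 0.5, 0, 0), noise_sd = 0, seed = 2)
  fit <- fit_triplet(st$tv)
  expect_equal(unname(fit$beta), c(2, 0.5, 0, 0), tolerance = 1e-10)

  # constant modulator after transform -> rank-deficient, not a crash
  tv <- list(x_tf = rnorm(30, 8, 2), x_m = rep(1, 30),
             y_target = rnorm(30, 8, 2))
  tv$n <- 30L
  un <- fit_triplet(tv)
  expect_identical(un$status, "unfit")
  expect_match(un$reason, "rank-deficient")

  # too few samples for any residual df
  tiny <- simulate_triplet(4, seed = 3)$tv
  expect_identical(fit_triplet(tiny)$status, "unfit")
})

test_that("scan covers the pair x event cross and records skips", {
  sim <- simulate_dataset(sim_config(n_samples = 60, n_tfs = 2,
                                     n_targets_per_tf = 3, n_events = 2,
                                     missing_rate = 0, seed = 9))
  res <- scan_all(sim$expression, sim$psi, sim$pairs,
                  min_samples_gene = 30, min_samples_triplet = 20)
  expect_identical(nrow(res), 12L)  # 6 pairs x 2 events
  expect_true(all(res$status == "fit"))
  # deterministic lexicographic order
  key <- paste(res$tf, res$target, res$event)
  expect_identical(key, sort(key, method = "radix"))

  # a target lacking an expression row is reported skipped, not dropped
  pairs2 <- rbind(sim$pairs, data.frame(tf = "TF001", target = "GHOST"))
  res2 <- scan_all(sim$expression, sim$psi, pairs2,
                   min_samples_gene = 30, min_samples_triplet = 20)
  ghost <- res2[res2$target == "GHOST", ]
  expect_identical(nrow(ghost), 2L)
  expect_true(all(ghost$status == "skipped"))
  expect_match(ghost$reason[1], "not in expression")

  # gene-eligibility threshold knocks out low-coverage genes
  res3 <- scan_all(sim$expression, sim$psi, sim$pairs,
                   min_samples_gene = 61, min_samples_triplet = 20)
  expect_true(all(res3$status == "skipped"))

  expect_warning(scan_all(sim$expression, sim$psi,
                          sim$pairs[0, ], min_samples_gene = 30),
                 "empty")
})

test_that("scan output is invariant to input row/column ordering", {
  sim <- simulate_dataset(sim_config(n_samples = 50, n_tfs = 2,
                                     n_targets_per_tf = 2, n_events = 2,
                                     missing_rate = 0.05, seed = 21))
  base <- scan_all(sim$expression, sim$psi, sim$pairs,
                   min_samples_gene = 10, min_samples_triplet = 10)
  set.seed(1)
  rp <- sample(nrow(sim$expression)); cp <- sample(ncol(sim$expression))
  ep <- sample(nrow(sim$psi))
  psi_perm <- sim$psi[ep, cp]
  attr(psi_perm, "event_gene") <- attr(sim$psi, "event_gene")
  perm <- scan_all(sim$expression[rp, cp], psi_perm,
                   sim$pairs[sample(nrow(sim$pairs)), ],
                   min_samples_gene = 10, min_samples_triplet = 10)
  expect_equal(perm, base)
})

test_that("planted interactions surface with the smallest p-values", {
  # 100 designated triplets, 5 modulated at a large effect
  sim <- simulate_dataset(sim_config(n_samples = 400, n_tfs = 5,
                                     n_targets_per_tf = 20, n_events = 1,
                                     frac_modulated = 0.05, beta3_effect = 1.5,
                                     noise_sd = 1, missing_rate = 0,
                                     seed = 33))
  res <- scan_all(sim$expression, sim$psi, sim$pairs,
                  min_samples_gene = 400, min_samples_triplet = 30)
  expect_true(all(res$status == "fit"))
  truth <- sim$truth[match(paste(res$target, res$event),
                           paste(sim$truth$target, sim$truth$event)), ]
  top5 <- res$target[order(res$p3)][1:5]
  expect_setequal(top5, truth$target[truth$modulated])
})

test_that("BH correction matches the hand-computed step-up and the rules of the scan", {
  res <- data.frame(tf = "a", target = letters[1:4], event = "e",
                    event_gene = NA_character_, status = "fit",
                    reason = NA_character_, n = 50L,
                    beta0 = 0, beta1 = 0, beta2 = 0,
                    beta3 = c(1, -1, 2, 0.5),
                    se3 = 1, t3 = 1, p3 = c(0.01, 0.02, 0.03, 0.9),
                    stringsAsFactors = FALSE)
  out <- correct_fdr(res, alpha = 0.05)
  expect_equal(out$q3, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(out$q3, bh_oracle(res$p3))
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(out$sign, c("positive", "negative", "positive", NA))

  # all-null scan: nothing called
  res$p3 <- rep(1, 4)
  expect_false(any(correct_fdr(res)$significant))

  # single test: q equals p
  one <- res[1, ]; one$p3 <- 0.04
  out1 <- correct_fdr(one)
  expect_equal(out1$q3, 0.04)
  expect_true(out1$significant)

  # p-value mode bypasses the correction
  res$p3 <- c(0.005, 0.02, 0.5, 0.9)
  pv <- correct_fdr(res, alpha = 0.01, mode = "pvalue")
  expect_identical(pv$significant, c(TRUE, FALSE, FALSE, FALSE))

  # skipped rows keep NA q-values and never enter the correction
  res$status[4] <- "skipped"
  out2 <- correct_fdr(res)
  expect_true(is.na(out2$q3[4]))
  expect_equal(out2$q3[1:3], bh_oracle(res$p3[1:3]))
})
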