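test_that("PSI split takes the bottom/top fraction with deterministic ties", {
  v <- setNames(seq(0.1, 1.0, by = 0.1), paste0("s", 1:10))
  grp <- split_by_psi(v, 0.3)
  expect_identical(grp$low, c("s1", "s2", "s3"))
  expect_identical(grp$high, c("s8", "s9", "s10"))
  expect_length(intersect(grp$low, grp$high), 0)

  # floor semantics: n = 5, f = 0.3 -> 1 per group
  v5 <- setNames(c(0.5, 0.2, 0.9, 0.1, 0.7), paste0("s", 1:5))
  g5 <- split_by_psi(v5, 0.3)
  expect_identical(g5$low, "s4")
  expect_identical(g5$high, "s3")

  # all-equal PSI: tie-broken by sample id, with a warning
  ve <- setNames(rep(0.5, 10), paste0("s", sprintf("%02d", 1:10)))
  expect_warning(ge <- split_by_psi(ve, 0.3), "tie")
  expect_identical(ge$low, names(ve)[1:3])
  expect_identical(ge$high, names(ve)[8:10])

  expect_error(split_by_psi(setNames(c(0.1, 0.9), c("a", "b")), 0.3),
               "at least")
  expect_error(split_by_psi(setNames(runif(3), letters[1:3]), 0.7),
               "overlap")
})

test_that("correlation states follow the sign and significance of r", {
  x <- setNames(seq_len(10) + 0, paste0("s", 1:10))
  expect_identical(correlation_state(x, x, names(x))$state, "+")
  st <- correlation_state(x, x, names(x))
  expect_equal(st$r, 1)

  set.seed(4)
  xx <- setNames(rnorm(50), paste0("s", 1:50))
  yy <- setNames(-xx + rnorm(50, 0, 0.2), names(xx))
  expect_identical(correlation_state(xx, yy, names(xx))$state, "-")

  # zero-variance vector: Non-sig with undefined r
  cz <- correlation_state(setNames(rep(1, 5), letters[1:5]),
                          setNames(rnorm(5), letters[1:5]), letters[1:5])
  expect_identical(cz$state, "Non-sig")
  expect_true(is.na(cz$r))

  # independent x, y: Non-sig with probability ~ 1 - alpha
  set.seed(5)
  states <- replicate(200, {
    a <- setNames(rnorm(100), paste0("s", 1:100))
    b <- setNames(rnorm(100), paste0("s", 1:100))
    correlation_state(a, b, names(a))$state
  })
  expect_gt(mean(states == "Non-sig"), 0.9)
})

test_that("mode-of-action categories follow the transition rules", {
  # one planted triplet per transition label at a well-separated effect
  for (kind in moa_transitions()) {
    tt <- simulate_transition_triplet(kind, n = 200, effect = 0.8,
                                      seed = 17)
    cl <- classify_triplet(tt$tv, tt$psi_raw, tt$beta3)
    expect_identical(cl$transition, kind, label = kind)
    expect_identical(cl$category, tt$expected$category, label = kind)
    expect_identical(cl$sign, tt$sign, label = kind)
    if (cl$category == "Repress")
      expect_identical(cl$reduced, tt$expected$reduced, label = kind)
  }

  # same-sign with equal correlation magnitude: Repress, not reduced
  tt <- simulate_transition_triplet("+->+", n = 200, effect = 0.8,
                                    seed = 18, r_low = 0.8, r_high = 0.8)
  cl <- classify_triplet(tt$tv, tt$psi_raw, beta3 = 1)
  expect_identical(cl$category, "Repress")
  expect_false(cl$reduced)

  # groups below the minimum: Uncalled with a reason
  tiny <- simulate_transition_triplet("Non-sig->+", n = 12, effect = 0.8,
                                      seed = 19)
  cl2 <- classify_triplet(tiny$tv, tiny$psi_raw, 1, min_group = 5)
  expect_identical(cl2$category, "Uncalled")
  expect_match(cl2$reason, "group size")
})

test_that("negating the target flips states but preserves category structure", {
  for (kind in c("Non-sig->+", "+->-", "+->+")) {
    tt <- simulate_transition_triplet(kind, n = 200, effect = 0.8, seed = 23)
    cl <- classify_triplet(tt$tv, tt$psi_raw, tt$beta3)
    neg <- tt$tv
    neg$y_target <- -neg$y_target
    cln <- classify_triplet(neg, tt$psi_raw, -tt$beta3)
    flip <- function(s) switch(s, "+" = "-", "-" = "+", "Non-sig" = "Non-sig")
    expect_identical(cln$state_low, flip(cl$state_low))
    expect_identical(cln$state_high, flip(cl$state_high))
    expect_identical(cln$category, cl$category)
    expect_false(identical(cln$sign, cl$sign))
  }
})

test_that("classify_all partitions significant triplets into the summary cells", {
  sim <- simulate_dataset(sim_config(n_samples = 200, n_tfs = 2,
                                     n_targets_per_tf = 10, n_events = 2,
                                     frac_modulated = 0.2, beta3_effect = 1.5,
                                     missing_rate = 0, seed = 41))
  res <- correct_fdr(scan_all(sim$expression, sim$psi, sim$pairs,
                              min_samples_gene = 100,
                              min_samples_triplet = 30))
  cls <- classify_all(res, sim$expression, sim$psi)
  n_sig <- sum(res$significant %in% TRUE)
  expect_identical(nrow(cls$calls), n_sig)
  # every call lands in exactly one (sign x category) cell
  cells <- as.matrix(cls$summary[, c("Active", "Repress", "Inverts",
                                     "Uncalled")])
  expect_identical(sum(cells), n_sig)
  expect_identical(cls$summary$sign, c("positive", "negative"))

  # no significant triplets -> all-zero table
  none <- correct_fdr(res[res$status == "fit", ][0, ])
  cls0 <- classify_all(none, sim$expression, sim$psi)
  expect_identical(nrow(cls0$calls), 0L)
  expect_true(all(as.matrix(cls0$summary[, -1]) == 0))
})
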