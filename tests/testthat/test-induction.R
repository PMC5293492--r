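make_expr <- function(features, values_by_sample, reference = "snoRNA-202",
                      ref_value = 100) {
  rows <- list()
  for (s in names(values_by_sample)) {
    gr <- sub(":.*", "", s)
    rep_ <- as.integer(sub(".*:", "", s))
    rows[[s]] <- data.frame(
      feature = c(features, reference), group = gr, replicate = rep_,
      value = c(values_by_sample[[s]], ref_value), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("reference normalization and naive folding behave as ratios", {
  samples <- c("naive:1", "naive:2", "immediate:1", "immediate:2",
               "trained:1", "trained:2")
  # every feature equal to the reference in every sample -> folds all 1
  ex <- make_expr("f1", setNames(as.list(rep(100, 6)), samples))
  fc <- normalize_and_fold(ex)
  expect_equal(fc$fold, rep(1, 6))
  # doubling all raw values of one sample changes nothing
  ex2 <- make_expr(c("f1", "f2"),
                   setNames(list(c(10, 20), c(10, 22), c(30, 40), c(28, 41),
                                 c(50, 60), c(52, 58)), samples))
  ex2_scaled <- ex2
  pick <- ex2_scaled$group == "trained" & ex2_scaled$replicate == 1
  ex2_scaled$value[pick] <- ex2_scaled$value[pick] * 2
  expect_equal(normalize_and_fold(ex2)$fold, normalize_and_fold(ex2_scaled)$fold)
  # naive-group mean fold is 1 per feature by construction
  fc2 <- normalize_and_fold(ex2)
  for (f in c("f1", "f2")) {
    expect_equal(mean(fc2$fold[fc2$feature == f & fc2$group == "naive"]), 1)
  }
})

test_that("RNU58 is accepted as reference alias; bad references fail loudly", {
  samples <- c("naive:1", "naive:2", "trained:1", "trained:2")
  ex <- make_expr("f1", setNames(as.list(rep(50, 4)), samples),
                  reference = "RNU58")
  expect_silent(fc <- normalize_and_fold(ex))
  expect_equal(fc$fold, rep(1, 4))
  expect_error(normalize_and_fold(make_expr("f1",
    setNames(as.list(rep(50, 4)), samples), reference = "other")),
    "not found")
  ex_zero <- make_expr("f1", setNames(as.list(rep(50, 4)), samples),
                       ref_value = 0)
  expect_error(normalize_and_fold(ex_zero), "naive:1")
})

test_that("the induction filter is all-replicates and boundary inclusive", {
  fc <- rbind(make_fc("a", c(1, 1, 1), c(1, 1, 1), c(1.6, 1.7, 1.5)),
              make_fc("b", c(1, 1, 1), c(1, 1, 1), c(1.6, 1.7, 1.4)))
  ind <- detect_induced(fc, theta = 1.5)
  expect_true(ind[["a"]])
  expect_false(ind[["b"]])
  # relaxed rule: 2 of 3 replicates suffice
  expect_true(detect_induced(fc, theta = 1.5, n_required = 2)[["b"]])
})

test_that("detection rate matches an independently simulated expectation", {
  # planted per-replicate fold = 1.8 x lognormal(CV 0.1), folds recomputed
  # against the realized naive mean as the pipeline does
  cv <- 0.1
  sigma <- sqrt(log(1 + cv^2))
  sim_feature <- function() {
    naive <- stats::rlnorm(3, -sigma^2 / 2, sigma)
    trained <- 1.8 * stats::rlnorm(3, -sigma^2 / 2, sigma)
    trained / mean(naive)
  }
  withr::with_seed(101, {
    expected <- mean(replicate(20000, all(sim_feature() >= 1.5)))
  })
  withr::with_seed(202, {
    observed <- mean(vapply(1:200, function(i) {
      f <- sim_feature()
      detect_induced(make_fc("x", c(1, 1, 1), c(1, 1, 1), f))[["x"]]
    }, logical(1)))
  })
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("class assignment reproduces the three textbook patterns", {
  jit <- c(1.001, 0.999, 1.0005)  # minimal noise so the tests are defined
  fc1 <- make_fc("c1", c(1, 1.01, 0.99), 1 * jit, 3 * c(1.0, 1.02, 0.98))
  fc2 <- make_fc("c2", c(1, 1.01, 0.99), c(1.8, 1.9, 2.0), c(3.0, 3.1, 2.9))
  fc3 <- make_fc("c3", c(1, 1.01, 0.99), c(1.9, 2.1, 2.0), c(2.0, 2.1, 1.9))
  r1 <- classify_induction(fc1)
  r2 <- classify_induction(fc2)
  r3 <- classify_induction(fc3)
  expect_identical(r1$class, "I")
  expect_identical(r2$class, "II")
  expect_identical(r3$class, "III")
  # p-values equal the textbook Welch computation on log folds
  g <- function(fc, grp) log(fc$fold[fc$group == grp])
  expect_equal(r2$p_trained_vs_naive,
               oracle_welch_p(g(fc2, "trained"), g(fc2, "naive")))
  expect_equal(r2$p_immediate_vs_naive,
               oracle_welch_p(g(fc2, "immediate"), g(fc2, "naive")))
  expect_equal(r2$p_trained_vs_immediate,
               oracle_welch_p(g(fc2, "trained"), g(fc2, "immediate")))
  # geometric-mean group summaries
  expect_equal(r2$fold_trained, exp(mean(g(fc2, "trained"))))
  expect_equal(r2$fold_immediate, exp(mean(g(fc2, "immediate"))))
})

test_that("class labels partition induced features and respect preconditions", {
  fc <- rbind(
    make_fc("up", c(1, 1.01, 0.99), c(1.0, 1.02, 0.98), c(3.0, 3.1, 2.9)),
    make_fc("flat", c(1, 1.01, 0.99), c(1.0, 1.02, 0.98), c(1.0, 1.05, 0.97)))
  res <- classify_induction(fc)
  expect_true(all(res$class[res$class %in% c("I", "II", "III")] ==
                    res$class[res$induced & res$class != "unclassified"]))
  expect_identical(res$class[res$feature == "flat"], "unclassified")
  expect_false(res$induced[res$feature == "flat"])
  # missing group
  expect_error(classify_induction(fc[fc$group != "immediate", ]), "immediate")
  # fewer than two replicates in a group
  fc_bad <- make_fc("x", c(1, 1), c(1.5), c(2, 2.1))
  expect_error(classify_induction(fc_bad), "fewer than 2")
})

test_that("classification is invariant to per-sample rescaling of raw data", {
  cfg <- sim_config(seed = 31, n_mirnas = 4, n_background_features = 3)
  ex <- simulate_expression(cfg)$expression
  res1 <- classify_induction(normalize_and_fold(ex))
  ex2 <- ex
  for (s in unique(paste(ex2$group, ex2$replicate))) {
    pick <- paste(ex2$group, ex2$replicate) == s
    ex2$value[pick] <- ex2$value[pick] * stats::runif(1, 0.2, 5)
  }
  res2 <- classify_induction(normalize_and_fold(ex2))
  expect_equal(res1, res2)
})
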