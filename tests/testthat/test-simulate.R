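test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(n_up = 20, n_down = 20, n_shared = 20,
                           n_silent = 5, n_activatome = 5, n_erasome = 5)
  a <- simulate_experiment(cfg, seed = 61)
  b <- simulate_experiment(cfg, seed = 61)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_experiment(cfg, seed = 62)
  expect_false(identical(a$counts$counts, c$counts$counts))
  expect_equal(attr(a$counts, "seed"), 61)
})

test_that("zero dispersion collapses the counts to Poisson behavior", {
  cfg <- simulation_config(n_up = 0, n_down = 0, n_shared = 2000,
                           n_silent = 0, n_activatome = 0, n_erasome = 0,
                           dispersion = 0, size_factor_sdlog = 0,
                           baseline_meanlog = log(500), baseline_sdlog = 0)
  sim <- simulate_experiment(cfg, seed = 63)
  x <- sim$counts$counts[, 1]
  expect_equal(var(x) / mean(x), 1, tolerance = 0.1)
  disp <- simulate_experiment(simulation_config(
    n_up = 0, n_down = 0, n_shared = 2000, n_silent = 0, n_activatome = 0,
    n_erasome = 0, dispersion = 0.05, size_factor_sdlog = 0,
    baseline_meanlog = log(500), baseline_sdlog = 0), seed = 63)
  y <- disp$counts$counts[, 1]
  # NB variance mu + alpha mu^2 well above Poisson at mu = 500
  expect_gt(var(y) / mean(y), 5)
})

test_that("planted silent genes are recovered as silent_both", {
  sim <- simulate_experiment(simulation_config(n_up = 30, n_down = 30,
                                               n_shared = 60,
                                               n_silent = 100,
                                               n_activatome = 0,
                                               n_erasome = 0), seed = 64)
  res <- run_pipeline(sim$counts)
  sil <- sim$truth$gene[sim$truth$class == "silent_both"]
  called <- res$partition$class[match(sil, res$partition$gene)]
  expect_gte(mean(called == "silent_both"), 0.99)
})

test_that("estimated fold changes of planted enriched genes are unbiased", {
  # a non-DE background keeps the median-of-ratios reference identifiable
  cfg <- simulation_config(n_up = 500, n_down = 500, n_shared = 1000,
                           n_silent = 0, n_activatome = 0, n_erasome = 0,
                           lfc = 2, dispersion = 0.05,
                           replicates = c(start = 4, vector_control = 2,
                                          reprogramming = 2, target = 4))
  sim <- simulate_experiment(cfg, seed = 65)
  cm <- normalize_counts(sim$counts)
  de <- contrast_stats(cm, cond_num = "target", cond_den = "start")
  up <- sim$truth$class == "up"
  bias <- mean(de$lfc[up] - sim$truth$lfc[up])
  expect_lt(abs(bias), 0.1)
})

test_that("recovery evaluation reports confusions faithfully", {
  truth <- data.frame(gene = paste0("g", 1:6),
                      class = c("up", "up", "down", "shared", "shared",
                                "silent_both"),
                      category = c("proper_up", "no_response", "proper_down",
                                   "no_response", "unwanted_up",
                                   "not_applicable"),
                      stringsAsFactors = FALSE)
  perfect <- data.frame(gene = truth$gene, class = truth$class,
                        tier = NA, in_activatome = FALSE, in_erasome = FALSE,
                        lfc = 0, q = 1, stringsAsFactors = FALSE)
  rec <- evaluate_recovery(truth, perfect)
  expect_true(all(rec$class_sensitivity[c("up", "down", "shared",
                                          "silent_both")] == 1))
  expect_equal(rec$false_enrichment_rate, 0)
  expect_equal(sum(rec$class_confusion) - sum(diag(rec$class_confusion)), 0)

  # degenerate caller: every response collapsed onto no_response
  calls <- data.frame(gene = truth$gene[1:5], class = truth$class[1:5],
                      category = "no_response", stringsAsFactors = FALSE)
  rec2 <- evaluate_recovery(truth, perfect, calls)
  expect_equal(sum(rec2$piano_confusion[, "no_response"]), 5)
  expect_equal(sum(rec2$piano_confusion), 5)  # silent gene has no call
  expect_equal(unname(rec2$piano_recall["proper_up"]), 0)
})

test_that("malformed simulation configs are rejected", {
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(simulation_config(replicates = c(start = 1, vector_control = 2,
                                                reprogramming = 2,
                                                target = 2)),
               "2 replicates")
  expect_error(simulation_config(completeness = list(
    up = c(proper = 0.5, insufficient = 0, none = 0, wrong = 0, over = 0),
    down = c(proper = 1, insufficient = 0, none = 0, wrong = 0, over = 0),
    shared = c(none = 1, unwanted_up = 0, unwanted_down = 0))),
    "sum to 1")
  expect_error(simulate_experiment(simulation_config()), "seed")
})
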