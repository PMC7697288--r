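cfg <- preset_thresholds("strict")

test_that("the decision table reproduces the canonical response patterns", {
  # upregulated significantly but still far short of the target level
  expect_equal(gene_response("up", fc_start = 2.5, fc_control = 2.4,
                             fc_target = 1 / 13.3, p_start = 0.001,
                             cfg = cfg),
               "insufficient_up")
  # shared gene induced beyond both controls and above the target level
  expect_equal(gene_response("shared", 2.6, 2.2, 2.6, 0.01, cfg = cfg),
               "unwanted_up")
  # start-enriched gene significantly upregulated instead of silenced
  expect_equal(gene_response("down", 3.1, 2.8, 2.0, 0.001, cfg = cfg),
               "wrong_up")
  # target-enriched gene barely moved
  expect_equal(gene_response("up", 1.2, 1.3, 0.2, 0.001, cfg = cfg),
               "no_response")
  # strong induction landing at the target level
  expect_equal(gene_response("up", 4, 4, 1 / 1.1, 0.001, cfg = cfg),
               "proper_up")
  # overshoot needs a significant reprogramming-vs-target gap
  expect_equal(gene_response("up", 8, 8, 2.1, 0.001, p_target = 0.4,
                             cfg = cfg), "proper_up")
  expect_equal(gene_response("up", 8, 8, 2.1, 0.001, p_target = 0.01,
                             cfg = cfg), "over_up")
  # mirrored down-class calls
  expect_equal(gene_response("down", 1 / 3, 1 / 3, 1.1, 0.001, cfg = cfg),
               "proper_down")
  expect_equal(gene_response("down", 1 / 2, 1 / 2, 3, 0.001, cfg = cfg),
               "insufficient_down")
  expect_equal(gene_response("up", 1 / 3, 1 / 3, 1 / 20, 0.001, cfg = cfg),
               "wrong_down")
  expect_equal(gene_response("shared", 1 / 4, 1 / 4, 1 / 4, 0.01, cfg = cfg),
               "unwanted_down")
  # silent and uncertain genes are out of scope for the table
  expect_equal(gene_response(c("silent_both", "uncertain"), 4, 4, 1, 0.001,
                             cfg = cfg),
               c("not_applicable", "not_applicable"))
})

test_that("a response must clear both the start and vector-control bars", {
  # induced vs start but not vs the vector control: an artifact, not a response
  expect_equal(gene_response("up", 4, 1.2, 1, 0.001, cfg = cfg),
               "no_response")
  # mixed directions between the references never count as a response
  expect_equal(gene_response("up", 2, 1 / 2, 1, 0.001, cfg = cfg),
               "no_response")
  # insignificant change is no response however large
  expect_equal(gene_response("up", 6, 6, 1, 0.2, cfg = cfg), "no_response")
})

test_that("every fold/significance combination yields exactly one category", {
  fcs <- c(0.1, 1 / 2, 1 / 1.5, 0.9, 1, 1.2, 1.5, 2, 3)
  ps <- c(0.001, 0.05, 0.5, NA)
  classes <- c("up", "down", "shared", "silent_both", "uncertain")
  grid <- expand.grid(fs = fcs, fc = fcs, ft = fcs, p = ps, cl = classes,
                      stringsAsFactors = FALSE)
  cat <- gene_response(grid$cl, grid$fs, grid$fc, grid$ft, grid$p,
                       p_target = 0.01, cfg = cfg)
  allowed <- c("proper_up", "proper_down", "insufficient_up",
               "insufficient_down", "over_up", "over_down", "wrong_up",
               "wrong_down", "unwanted_up", "unwanted_down", "no_response",
               "not_applicable")
  expect_true(all(cat %in% allowed))
  expect_length(cat, nrow(grid))
  # direction coherence
  expect_true(all(grid$cl[cat %in% c("proper_up", "insufficient_up",
                                     "over_up", "wrong_down")] == "up"))
  expect_true(all(grid$cl[cat %in% c("proper_down", "insufficient_down",
                                     "over_down", "wrong_up")] == "down"))
  expect_true(all(grid$cl[grepl("^unwanted", cat)] == "shared"))
})

test_that("no up-class gene is called wrong_down when reprogramming completes", {
  sim <- simulate_experiment(
    simulation_config(n_up = 120, n_down = 0, n_shared = 1000, n_silent = 0,
                      n_activatome = 0, n_erasome = 0,
                      completeness = list(
                        up = c(proper = 0.85, insufficient = 0.05,
                               none = 0.10, wrong = 0, over = 0),
                        down = c(proper = 1, insufficient = 0, none = 0,
                                 wrong = 0, over = 0),
                        shared = c(none = 1, unwanted_up = 0,
                                   unwanted_down = 0)),
                      replicates = c(start = 4, vector_control = 4,
                                     reprogramming = 4, target = 3)),
    seed = 31)
  res <- run_pipeline(sim$counts)
  up_calls <- res$piano$category[res$piano$class == "up"]
  expect_false(any(up_calls == "wrong_down"))
})

test_that("threshold sensitivity scans behave monotonically", {
  sim <- simulate_experiment(
    simulation_config(n_up = 80, n_down = 80, n_shared = 80, n_silent = 0,
                      n_activatome = 0, n_erasome = 0,
                      completeness = list(
                        up = c(proper = 0.5, insufficient = 0.3, none = 0.2,
                               wrong = 0, over = 0),
                        down = c(proper = 0.5, insufficient = 0.3,
                                 none = 0.2, wrong = 0, over = 0),
                        shared = c(none = 1, unwanted_up = 0,
                                   unwanted_down = 0)),
                      replicates = c(start = 4, vector_control = 4,
                                     reprogramming = 4, target = 3)),
    seed = 32)
  res <- run_pipeline(sim$counts)
  de <- res$de
  sens <- threshold_sensitivity(de$reprog_vs_start, de$reprog_vs_control,
                                de$reprog_vs_target, res$partition,
                                grid = data.frame(respond_fc = c(1.5, 1.5),
                                                  proximity_fc = c(1.5, 2),
                                                  respond_p = c(0.05, 0.05)))
  ins <- sens$insufficient_up + sens$insufficient_down
  # widening the proximity window never increases the insufficient count
  expect_lte(ins[2], ins[1])

  # a degenerate grid of the in-force setting reproduces classify_all counts
  one <- threshold_sensitivity(de$reprog_vs_start, de$reprog_vs_control,
                               de$reprog_vs_target, res$partition,
                               grid = data.frame(respond_fc = 1.5,
                                                 proximity_fc = 1.5,
                                                 respond_p = 0.05))
  tab <- table(res$piano$category)
  for (k in names(tab)) expect_equal(one[[k]], unname(tab[k]))

  # an unreachable response bar drives every enriched gene to no_response
  hard <- threshold_sensitivity(de$reprog_vs_start, de$reprog_vs_control,
                                de$reprog_vs_target, res$partition,
                                grid = data.frame(respond_fc = 1e9,
                                                  proximity_fc = 1.5,
                                                  respond_p = 0.05))
  enriched_cats <- c("proper_up", "proper_down", "insufficient_up",
                     "insufficient_down", "over_up", "over_down",
                     "wrong_up", "wrong_down")
  expect_true(all(unlist(hard[enriched_cats]) == 0))
})
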