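strict <- preset_thresholds("strict")
lenient <- preset_thresholds("lenient")

test_that("constructed genes land in their sub-reprogramomes", {
  de <- make_de(gene = c("up4x", "acto", "small", "uncert", "sil"),
                mean_num = c(400, 800, 105, 170, 3),
                mean_den = c(100, 2, 100, 100, 2),
                p = c(0.001, 1e-6, 0.9, 0.02, 0.9),
                q = c(0.001, 1e-6, 0.9, 0.02, 0.9))
  act_s <- make_activity(de$gene, c("active", "inactive", "active",
                                    "active", "inactive"))
  act_t <- make_activity(de$gene, c("active", "active", "active",
                                    "active", "inactive"), "target")
  part <- partition_reprogramome(de, act_s, act_t, strict)
  expect_equal(part$class,
               c("up", "up", "shared", "uncertain", "silent_both"))
  # activatome only for genes switched on from silence
  expect_equal(part$in_activatome, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(any(part$in_erasome))
  # 1.7x at q = 0.02 is unresolved at strict tier, up at the lenient tier
  tiered <- tiered_partition(de, act_s, act_t, strict, lenient)
  expect_equal(tiered$class[4], "up")
  expect_equal(tiered$tier[4], "lenient")
  expect_equal(tiered$class[1], "up")
  expect_equal(tiered$tier[1], "strict")
})

test_that("the partition is exhaustive and exclusive on simulated data", {
  sim <- simulate_experiment(simulation_config(n_up = 40, n_down = 40,
                                               n_shared = 80, n_silent = 10,
                                               n_activatome = 10,
                                               n_erasome = 10), seed = 9)
  res <- run_pipeline(sim$counts)
  counts <- partition_counts(res$partition)
  expect_equal(sum(counts[c("up", "down", "shared", "silent_both",
                            "uncertain")]),
               nrow(res$partition))
  # activatome within up, erasome within down
  expect_true(all(res$partition$class[res$partition$in_activatome] == "up"))
  expect_true(all(res$partition$class[res$partition$in_erasome] == "down"))
  # silent genes are inactive in both cell types
  sil <- res$partition$gene[res$partition$class == "silent_both"]
  pg <- res$per_gene
  expect_true(all(pg$active_start[pg$gene %in% sil] == "inactive"))
  expect_true(all(pg$active_target[pg$gene %in% sil] == "inactive"))
})

test_that("tightening thresholds never recruits genes into enrichment", {
  set.seed(21)
  n <- 60
  de <- make_de(gene = paste0("g", 1:n),
                mean_num = runif(n, 20, 2000),
                mean_den = runif(n, 20, 2000),
                p = runif(n)^2, q = runif(n)^2)
  de$q <- pmax(de$q, de$p)
  act <- make_activity(de$gene, "active")
  grid_fc <- c(1.3, 1.5, 2, 3)
  grid_q <- c(0.1, 0.05, 0.01)
  for (i in seq_along(grid_fc)[-1]) {
    for (j in seq_along(grid_q)[-1]) {
      loose <- partition_reprogramome(de, act, act,
        threshold_config(enrich_fc = grid_fc[i - 1], enrich_q = grid_q[j - 1]))
      tight <- partition_reprogramome(de, act, act,
        threshold_config(enrich_fc = grid_fc[i], enrich_q = grid_q[j]))
      newly <- tight$class %in% c("up", "down") &
        !(loose$class %in% c("up", "down"))
      expect_false(any(newly))
    }
  }
})

test_that("strict-tier enrichment calls are immutable under the lenient pass", {
  set.seed(22)
  n <- 80
  de <- make_de(gene = paste0("g", 1:n),
                mean_num = runif(n, 20, 2000), mean_den = runif(n, 20, 2000),
                p = runif(n)^3, q = runif(n)^3)
  de$q <- pmax(de$q, de$p)
  act <- make_activity(de$gene, "active")
  st <- partition_reprogramome(de, act, act, strict)
  ti <- tiered_partition(de, act, act, strict, lenient)
  strict_enriched <- st$class %in% c("up", "down")
  expect_equal(ti$class[strict_enriched], st$class[strict_enriched])
  expect_true(all(ti$tier[strict_enriched] == "strict"))
  expect_error(tiered_partition(de, act, act, lenient, strict), "stringent")
})
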