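test_that("cell enumeration reproduces the factorial design cardinalities", {
  pos <- grid_spec(mechanisms = list(mechanism("positive")))
  expect_identical(nrow(enumerate_cells(pos)), 72L)
  mixed <- grid_spec(mechanisms = lapply(seq(0, 1, 0.1),
                                         function(a) mechanism("mixed", a)))
  expect_identical(nrow(enumerate_cells(mixed)), 792L)
  one <- grid_spec(ratios = 4, tie_counts = 0,
                   mechanisms = list(mechanism("positive")))
  expect_identical(nrow(enumerate_cells(one)), 1L)
  # default full design: 13 mechanism settings x 72 = 936 cells
  expect_identical(nrow(enumerate_cells(grid_spec())), 936L)
})

test_that("cells are ordered by (mechanism, ratio, ties)", {
  g <- grid_spec(ratios = c(0, 1), tie_counts = c(0, 4),
                 mechanisms = list(mechanism("positive"),
                                   mechanism("mixed", 0.5)))
  cells <- enumerate_cells(g)
  expect_identical(cells$mechanism_index, rep(1:2, each = 4))
  expect_identical(cells$ratio, rep(c(0L, 0L, 1L, 1L), 2))
  expect_identical(cells$ties, rep(c(0L, 4L), 4))
})

test_that("grid validation rejects empty or out-of-range axes", {
  expect_error(grid_spec(ratios = integer(0)), "non-empty")
  expect_error(grid_spec(ratios = 9), "ratios")
  expect_error(grid_spec(tie_counts = 29), "tie_counts")
  expect_error(grid_spec(replicates = 0), "replicates")
  expect_error(grid_spec(mechanisms = list("positive")), "mechanism")
})

test_that("run counts and determinism hold on small grids", {
  g <- grid_spec(ratios = 3, tie_counts = 8,
                 mechanisms = list(mechanism("mixed", 0.5)),
                 replicates = 3, base_seed = 5)
  r1 <- run_sweep(g)
  expect_identical(nrow(r1), 3L)
  expect_identical(r1, run_sweep(g))
  g2 <- grid_spec(ratios = c(2, 6), tie_counts = c(0, 12),
                  mechanisms = list(mechanism("positive"),
                                    mechanism("negative")),
                  replicates = 4, base_seed = 5)
  r2 <- run_sweep(g2)
  expect_identical(nrow(r2), 2L * 2L * 2L * 4L)
  expect_true(all(r2$final_id_a >= 1 & r2$final_id_a <= 6))
  expect_true(all(r2$final_id_b >= 1 & r2$final_id_b <= 6))
})

test_that("per-run seeds are stable hashes, independent of grid shape", {
  g_small <- grid_spec(ratios = 4, tie_counts = 8,
                       mechanisms = list(mechanism("negative")),
                       replicates = 2, base_seed = 11)
  g_large <- grid_spec(ratios = 0:8, tie_counts = seq(0, 28, 4),
                       mechanisms = list(mechanism("positive"),
                                         mechanism("negative")),
                       replicates = 2, base_seed = 11)
  r_small <- run_sweep(g_small)
  r_large <- run_sweep(g_large)
  sub <- r_large[r_large$mechanism_kind == "negative" &
                   r_large$ratio == 4 & r_large$ties == 8, ]
  rownames(sub) <- NULL
  expect_identical(sub, r_small)
  expect_true(all(r_large$seed >= 1 & r_large$seed < 2^31))
})

test_that("a run record can be reproduced from its seed alone", {
  g <- grid_spec(ratios = 5, tie_counts = 16,
                 mechanisms = list(mechanism("mixed", 0.7)),
                 replicates = 3, base_seed = 21)
  r <- run_sweep(g)
  for (i in seq_len(nrow(r))) {
    set.seed(r$seed[i])
    net <- generate_network(8, r$ratio[i], r$ties[i])
    fin <- final_state(simulate_identity(net, mechanism("mixed", 0.7)))
    expect_equal(fin$id_a, r$final_id_a[i], tolerance = 1e-12)
    expect_equal(fin$id_b, r$final_id_b[i], tolerance = 1e-12)
  }
})

test_that("derive_seed is deterministic, spread out, and integer-ranged", {
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  seeds <- vapply(1:500, function(i) derive_seed(1, i), integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_error(derive_seed(1, 0.5), "integer")
})

test_that("summaries aggregate by cell with sample standard deviations", {
  records <- data.frame(
    ratio = 4L, ties = 0L, mechanism_kind = "positive", alpha = NA_real_,
    replicate = 1:3, seed = 1:3,
    final_id_a = c(3.5, 3.6, 3.7), final_id_b = c(6, 6, 6)
  )
  s <- summarize_runs(records)
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean_id_a, 3.6, tolerance = 1e-12)
  expect_equal(s$sd_id_a, sd(c(3.5, 3.6, 3.7)), tolerance = 1e-12)
  expect_equal(s$sd_id_b, 0)
  expect_identical(s$n_replicates, 3L)

  single <- records[1, ]
  s1 <- summarize_runs(single)
  expect_true(is.na(s1$sd_id_a) && is.na(s1$sd_id_b))

  # count conservation: one summary row per cell
  g <- grid_spec(ratios = c(1, 7), tie_counts = c(0, 28),
                 mechanisms = list(mechanism("positive"),
                                   mechanism("mixed", 0.5)),
                 replicates = 5, base_seed = 2)
  r <- run_sweep(g)
  expect_identical(nrow(summarize_runs(r)), nrow(enumerate_cells(g)))
})

test_that("degenerate cells summarize exactly as derived", {
  g <- grid_spec(ratios = c(0, 8), tie_counts = c(0, 12),
                 mechanisms = list(mechanism("positive")),
                 replicates = 10, base_seed = 3)
  s <- summarize_runs(run_sweep(g))
  r0 <- s[s$ratio == 0, ]
  expect_true(all(r0$mean_id_a == 3.5) && all(r0$sd_id_a == 0))
  # ratio 8, ties 0: deterministic saturation by step 25
  r8 <- s[s$ratio == 8 & s$ties == 0, ]
  expect_equal(r8$mean_id_a, 6, tolerance = 1e-9)
  expect_equal(r8$sd_id_a, 0, tolerance = 1e-12)
})

test_that("alpha and 1 - alpha give mirrored outcome surfaces", {
  # pathwise (strong form): under one draw sequence, id_b at alpha is the
  # reflection about 3.5 of id_a at 1 - alpha
  set.seed(14)
  for (i in 1:8) {
    net <- generate_network(8, sample(0:8, 1), sample(0:28, 1))
    s <- sample.int(1e6, 1)
    for (alpha in c(0, 0.2, 0.4)) {
      t1 <- simulate_identity(net, mechanism("mixed", alpha), seed = s)
      t2 <- simulate_identity(net, mechanism("mixed", 1 - alpha), seed = s)
      expect_equal(t1$id_b, 7 - t2$id_a, tolerance = 1e-9)
      expect_equal(t1$id_a, 7 - t2$id_b, tolerance = 1e-9)
    }
  }
  # Monte-Carlo (surface form) on a reduced grid
  mk <- function(a) grid_spec(ratios = c(2, 4, 6), tie_counts = c(0, 12, 28),
                              mechanisms = list(mechanism("mixed", a)),
                              replicates = 30, base_seed = 6)
  s4 <- summarize_runs(run_sweep(mk(0.4)))
  s6 <- summarize_runs(run_sweep(mk(0.6)))
  expect_equal(s4$mean_id_a, 7 - s6$mean_id_b, tolerance = 0.2)
  expect_equal(s4$mean_id_b, 7 - s6$mean_id_a, tolerance = 0.2)
})

test_that("culture ratio r mirrors ratio n - r across the two identifications", {
  g <- grid_spec(ratios = c(1, 3, 5, 7), tie_counts = c(0, 16),
                 mechanisms = list(mechanism("positive")),
                 replicates = 40, base_seed = 8)
  s <- summarize_runs(run_sweep(g))
  for (r in c(1, 3)) {
    for (tc in c(0, 16)) {
      a <- s$mean_id_a[s$ratio == r & s$ties == tc]
      b <- s$mean_id_b[s$ratio == 8 - r & s$ties == tc]
      expect_equal(a, b, tolerance = 0.2)
    }
  }
})

test_that("a lone same-culture alter keeps outcome spread stable across ties", {
  # the single culture-A alter can have no same-culture tie, so its influence
  # and hence the spread of outcomes cannot depend on the tie count
  g <- grid_spec(ratios = 1, tie_counts = seq(0, 28, 4),
                 mechanisms = list(mechanism("positive")),
                 replicates = 200, base_seed = 9)
  s <- summarize_runs(run_sweep(g))
  expect_lt(max(s$sd_id_a) - min(s$sd_id_a), 0.1)
})

test_that("runs.csv and summary.csv render with fixed 6-decimal formatting", {
  g <- grid_spec(ratios = 4, tie_counts = 8,
                 mechanisms = list(mechanism("positive")),
                 replicates = 2, base_seed = 10)
  r <- run_sweep(g)
  runs_path <- withr::local_tempfile(fileext = ".csv")
  sum_path <- withr::local_tempfile(fileext = ".csv")
  write_runs(r, runs_path)
  write_summary(summarize_runs(r), sum_path)
  runs_lines <- readLines(runs_path)
  expect_identical(runs_lines[1],
    "ratio,ties,mechanism_kind,alpha,replicate,seed,final_id_a,final_id_b")
  expect_match(runs_lines[2], ",[0-9]+\\.[0-9]{6},[0-9]+\\.[0-9]{6}$")
  expect_identical(readLines(sum_path)[1],
    "ratio,ties,mechanism_kind,alpha,mean_id_a,sd_id_a,mean_id_b,sd_id_b,n_replicates")
})
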