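test_that("mean and s.e.m. follow the n-1 convention", {
  expect_equal(meanSem(c(2, 2, 2)), list(mean = 2, sem = 0, n = 3L))
  ms <- meanSem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_warning(one <- meanSem(5), "fewer than 2")
  expect_true(is.na(one$sem))

  set.seed(83)
  v <- rnorm(50)
  # two-pass oracle
  m <- sum(v) / 50
  s <- sqrt(sum((v - m)^2) / 49)
  expect_equal(meanSem(v)$sem, s / sqrt(50), tolerance = 1e-12)
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  r <- tTestUnpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-9)
  expect_equal(r$stars, "")

  set.seed(89)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(7, mean = 0.8)
    ref <- t.test(a, b, var.equal = TRUE)
    mine <- tTestUnpaired(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    refW <- t.test(a, b)
    mineW <- tTestUnpaired(a, b, equalVar = FALSE)
    expect_equal(mineW$p, refW$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate and symmetric t-test cases behave", {
  same <- tTestUnpaired(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(deg <- tTestUnpaired(c(3, 3), c(4, 4)), "degenerate")
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)

  set.seed(97)
  a <- rnorm(6); b <- rnorm(6, 1)
  ab <- tTestUnpaired(a, b); ba <- tTestUnpaired(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("analytic p agrees with a 20000-draw permutation test", {
  set.seed(101)
  a <- rnorm(6, 0.5)
  b <- rnorm(6)
  obs <- abs(tTestUnpaired(a, b)$t)
  pooled <- c(a, b)
  set.seed(102)
  permT <- replicate(20000, {
    ix <- sample.int(12, 6)
    abs(tTestUnpaired(pooled[ix], pooled[-ix])$t)
  })
  pPerm <- mean(permT >= obs - 1e-12)
  expect_lt(abs(tTestUnpaired(a, b)$p - pPerm), 0.02)
})

test_that("type-I error of the replicate-level test is calibrated", {
  set.seed(103)
  reject <- vapply(seq_len(2000), function(i) {
    tTestUnpaired(rnorm(5), rnorm(5))$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("stars track the p-value thresholds exactly", {
  expect_equal(pStars(c(0.2, 0.049, 0.011, 0.009, NA)),
               c("", "*", "*", "**", ""))
})

test_that("origin plot translates every trajectory to zero", {
  es <- simulateExperiment(list(flow = biasOnParams(), noflow = WalkParams()),
                           nCells = 5, nReplicates = 1, seed = 107)
  gp <- plotTrajectoriesOrigin(es)
  df <- gp$data
  firsts <- do.call(rbind, lapply(split(df, df$cell_id), function(s) s[1, ]))
  expect_true(all(firsts$x == 0 & firsts$y == 0))
  expect_equal(length(unique(df$cell_id)), 10L)

  # x-reflection of the input reflects the plotted data
  trs <- lapply(trajectories(es), function(tr) {
    Trajectory(cellId(tr), frameTimes(tr),
               positions(tr) %*% diag(c(-1, 1)),
               condition = conditions(tr), replicate = replicates(tr))
  })
  gp2 <- plotTrajectoriesOrigin(trs)
  expect_equal(gp2$data$x, -df$x)
  expect_equal(gp2$data$y, df$y)
})

test_that("end-to-end report is complete, deterministic and self-consistent", {
  cfg <- defaultReportConfig(seed = 11L)
  cfg$exocytosis$n_cells <- 40L
  cfg$exocytosis$n_replicates <- 2L
  cfg$chemotaxis$n_cells <- 10L

  d1 <- withr::local_tempdir()
  s1 <- runReport(cfg, d1)
  expect_true(all(file.exists(file.path(d1, c(
    "per_cell_metrics.csv", "per_replicate_metrics.csv", "comparisons.csv",
    "persistence_ratios.csv", "exocytosis_time_course.csv",
    "chemotaxis_per_cell.csv", "summary.json", "report.log",
    "trajectories_origin.png")))))

  d2 <- withr::local_tempdir()
  runReport(cfg, d2)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))

  # summary delta x equals direct recomputation through the metrics module
  mo <- cfg$motility
  es <- simulateExperiment(
    list(WT_noflow = WalkParams(meanSpeed = mo$mean_speed, dt = mo$dt_s,
                                nSteps = mo$n_steps, turnSd = mo$turn_sd,
                                stepCv = mo$step_cv),
         WT_flow = WalkParams(meanSpeed = mo$mean_speed, dt = mo$dt_s,
                              nSteps = mo$n_steps, turnSd = mo$turn_sd,
                              stepCv = mo$step_cv,
                              biasStrength = mo$bias_strength,
                              targetMode = "fixed_direction",
                              target = mo$flow_direction),
         KO_noflow = WalkParams(meanSpeed = mo$mean_speed, dt = mo$dt_s,
                                nSteps = mo$n_steps, turnSd = mo$turn_sd,
                                stepCv = mo$step_cv),
         KO_flow = WalkParams(meanSpeed = mo$mean_speed, dt = mo$dt_s,
                              nSteps = mo$n_steps, turnSd = mo$turn_sd,
                              stepCv = mo$step_cv)),
    nCells = mo$n_cells, nReplicates = mo$n_replicates, seed = cfg$seed)
  rs <- summarizeReplicates(es)
  expect_equal(s1$delta_x_mean$WT_flow,
               mean(rs$delta_x[rs$condition == "WT_flow"]))
  expect_equal(s1$shear_stress_pa, shearStress(ChamberSpec()))
})
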