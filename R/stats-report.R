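#' Arithmetic mean and standard error of the mean
#'
#' s.e.m. is the sample standard deviation (n - 1 denominator) divided by
#' the square root of n — the "mean +/- s.e.m." of figure legends. With
#' fewer than two values the s.e.m. is undefined and returned as NA with a
#' warning.
#'
#' @param values numeric vector.
#' @return list with `mean`, `sem`, `n`.
#' @examples
#' meanSem(c(1, 2, 3))  # mean 2, sem 0.5774
#' @export
meanSem <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    warning("fewer than 2 values: s.e.m. undefined")
    return(list(mean = if (n) mean(values) else NA_real_, sem = NA_real_,
                n = n))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Significance stars
#'
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise (including NA).
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
pStars <- function(p) {
  out <- ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", "")))
  as.character(out)
}

#' Two-tailed unpaired Student t-test
#'
#' Pooled-variance (equal-variance) Student t by default, the study's
#' global comparison scheme; set `equalVar = FALSE` for Welch. Implemented
#' in closed form so the degenerate zero-variance cases are defined:
#' identical constant samples give t = 0, p = 1; constant samples with
#' different means give p = 0 flagged `degenerate = TRUE`.
#'
#' @param a,b numeric vectors (each n >= 2), typically per-replicate means.
#' @return object of class `statResult`: list with `mean` (per group),
#'   `sem` (per group), `t`, `df`, `p`, `stars`, `n` (per group),
#'   `degenerate`.
#' @examples
#' tTestUnpaired(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4, p = 0.288
#' @export
tTestUnpaired <- function(a, b, equalVar = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2, all(is.finite(a)), all(is.finite(b)))
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  degenerate <- FALSE
  if (equalVar) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) {
      tval <- 0; p <- 1
    } else {
      tval <- sign(m1 - m2) * Inf; p <- 0; degenerate <- TRUE
      warning("zero pooled variance with unequal means: degenerate t-test")
    }
  } else {
    tval <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(mean = c(m1, m2),
                 sem = c(stats::sd(a) / sqrt(n1), stats::sd(b) / sqrt(n2)),
                 t = tval, df = df, p = p, stars = pStars(p),
                 n = c(n1, n2), degenerate = degenerate),
            class = "statResult")
}

#' @export
print.statResult <- function(x, ...) {
  cat(sprintf("two-tailed unpaired t-test: t = %.4f, df = %.4g, p = %.4g %s\n",
              x$t, x$df, x$p, x$stars))
  cat(sprintf("  group means +/- s.e.m.: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)\n",
              x$mean[1], x$sem[1], x$n[1], x$mean[2], x$sem[2], x$n[2]))
  invisible(x)
}

#' Origin-anchored trajectory plot
#'
#' Each trajectory is translated to start at (0, 0) and drawn on
#' equal-aspect um axes, with an arrow indicating the flow direction — the
#' standard visual for flow-oriented versus random migration, faceted by
#' condition.
#'
#' @param set an [ExperimentSet] or list of [Trajectory].
#' @param flowDirection numeric(2) or NULL; direction of the arrow (the
#'   assay convention is `c(-1, 0)`, flow right to left).
#' @param arrowLength arrow length in um.
#' @return a ggplot object; its `$data` holds the translated coordinates
#'   (`x`, `y`, `cell_id`, `condition`).
#' @export
plotTrajectoriesOrigin <- function(set, flowDirection = c(-1, 0),
                                   arrowLength = 20) {
  trajs <- if (is(set, "ExperimentSet")) trajectories(set) else set
  stopifnot(length(trajs) >= 1)
  dfs <- lapply(trajs, function(tr) {
    p <- sweep(tr@positions, 2, tr@positions[1, ])
    data.frame(cell_id = tr@cellId, condition = tr@condition,
               x = p[, 1], y = p[, 2])
  })
  df <- do.call(rbind, dfs)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$cell_id)) +
    ggplot2::geom_path(linewidth = 0.3, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_bw()
  if (!is.null(flowDirection)) {
    u <- flowDirection / sqrt(sum(flowDirection^2)) * arrowLength
    lim <- max(abs(df$x), abs(df$y))
    gp <- gp + ggplot2::annotate(
      "segment", x = -u[1] / 2, y = lim, xend = u[1] / 2, yend = lim + u[2],
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  }
  gp
}

#' Default report configuration
#'
#' The synthetic study emulated by [runReport()] when no config is given:
#' a wild-type-like strain that orients against +x under flow
#' (heading-bias 0.3) and a knockout-like strain that does not, each with
#' and without flow; 15 cells x 5 replicates, 15-s frames for 10 min at
#' 2.5 um/min; the 4 Pa chamber; a small exocytosis study (WT-like two-fold
#' schedule vs flat KO-like schedule) and a micropipette chemotaxis study.
#'
#' @param seed integer(1).
#' @return nested list; see the YAML written by [runReport()] for the shape.
#' @export
defaultReportConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    motility = list(
      n_cells = 15L, n_replicates = 5L, dt_s = 15, n_steps = 40L,
      mean_speed = 2.5, turn_sd = 0.6, step_cv = 0.3,
      bias_strength = 0.3, flow_direction = c(-1, 0)),
    chamber = list(flow_rate = 14, viscosity = 0.001, height = 250,
                   width = 5.5),
    exocytosis = list(
      n_cells = 80L, n_replicates = 3L, timepoints = c(0, 2, 4),
      base_prevalence = 0.041, fold_peak_wt = 2, fold_peak_ko = 1,
      render_images = TRUE),
    chemotaxis = list(
      n_cells = 30L, n_replicates = 4L, dt_s = 20, n_steps = 30L,
      source = c(-300, 0), bias_strength = 0.2))
}

#' End-to-end synthetic study report
#'
#' Simulates (or ingests) a rheotaxis study, computes per-cell and
#' per-replicate metrics, runs the replicate-level comparisons, and writes
#' tables, figures and a machine-readable JSON summary:
#' per-cell and per-replicate CSVs, a comparison table (delta x and speed,
#' WT-like vs KO-like, flow and no-flow), persistence ratios, the chamber
#' shear stress, an exocytosis time-course table, a chemotaxis table and an
#' origin-anchored trajectory figure. A log records the seed, package
#' version and exclusion counts. Reruns with the same config are
#' bit-identical. P-values are reported without multiple-testing
#' correction (one caveat line is printed in the log).
#'
#' @param config a config list (see [defaultReportConfig()]) or the path to
#'   a YAML file with the same shape.
#' @param outdir output directory, created if needed.
#' @return invisibly, the summary list written to `summary.json`.
#' @export
runReport <- function(config = defaultReportConfig(), outdir = tempfile()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$seed))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- as.integer(config$seed)
  log <- c(sprintf("rheotax report, package version %s",
                   as.character(utils::packageVersion("rheotax"))),
           sprintf("seed: %d", seed),
           "caveat: p-values are not corrected for multiple testing")

  ## --- motility study -----------------------------------------------------
  mo <- config$motility
  mkWalk <- function(bias) {
    WalkParams(meanSpeed = mo$mean_speed, dt = mo$dt_s, nSteps = mo$n_steps,
               turnSd = mo$turn_sd, stepCv = mo$step_cv,
               biasStrength = bias,
               targetMode = if (bias > 0) "fixed_direction" else "none",
               target = as.numeric(mo$flow_direction))
  }
  es <- simulateExperiment(
    list(WT_noflow = mkWalk(0), WT_flow = mkWalk(mo$bias_strength),
         KO_noflow = mkWalk(0), KO_flow = mkWalk(0)),
    nCells = mo$n_cells, nReplicates = mo$n_replicates, seed = seed)
  cm <- cellMetrics(es)
  rs <- summarizeReplicates(cm)
  utils::write.csv(cm, file.path(outdir, "per_cell_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(rs, file.path(outdir, "per_replicate_metrics.csv"),
                   row.names = FALSE)

  repVals <- function(cond, col) rs[[col]][rs$condition == cond]
  cmp <- function(col) {
    flow <- tTestUnpaired(repVals("WT_flow", col), repVals("KO_flow", col))
    noflow <- tTestUnpaired(repVals("WT_noflow", col),
                            repVals("KO_noflow", col))
    data.frame(metric = col, comparison = c("flow", "noflow"),
               mean_wt = c(flow$mean[1], noflow$mean[1]),
               sem_wt = c(flow$sem[1], noflow$sem[1]),
               mean_ko = c(flow$mean[2], noflow$mean[2]),
               sem_ko = c(flow$sem[2], noflow$sem[2]),
               t = c(flow$t, noflow$t), df = c(flow$df, noflow$df),
               p = c(flow$p, noflow$p),
               stars = c(flow$stars, noflow$stars))
  }
  comparisons <- rbind(cmp("delta_x"), cmp("speed"))
  utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  ratios <- data.frame(
    strain = c("WT", "KO"),
    persistence_ratio = c(
      persistenceRatio(repVals("WT_flow", "persistence"),
                       repVals("WT_noflow", "persistence")),
      persistenceRatio(repVals("KO_flow", "persistence"),
                       repVals("KO_noflow", "persistence"))))
  utils::write.csv(ratios, file.path(outdir, "persistence_ratios.csv"),
                   row.names = FALSE)

  ch <- config$chamber
  sigma <- shearStress(ChamberSpec(ch$flow_rate, ch$viscosity, ch$height,
                                   ch$width))

  fig <- plotTrajectoriesOrigin(es,
                                flowDirection = as.numeric(mo$flow_direction))
  grDevices::png(file.path(outdir, "trajectories_origin.png"),
                 width = 1400, height = 1100, res = 160)
  print(fig)
  grDevices::dev.off()

  ## --- exocytosis study ---------------------------------------------------
  ex <- config$exocytosis
  exoTable <- NULL
  if (!is.null(ex)) {
    exoRows <- list()
    for (strain in c("WT", "KO")) {
      fold <- if (strain == "WT") ex$fold_peak_wt else ex$fold_peak_ko
      pp <- PatchSimParams(nCells = ex$n_cells,
                           basePrevalence = ex$base_prevalence,
                           foldPeak = fold,
                           timepoints = as.numeric(ex$timepoints),
                           seed = childSeed(seed, 101L,
                                            if (strain == "WT") 1L else 2L))
      calls <- if (isTRUE(ex$render_images)) {
        do.call(rbind, lapply(seq_len(ex$n_replicates), function(r) {
          pr <- pp
          pr@seed <- childSeed(pp@seed, r)
          scorePatchImages(renderPatchImages(pr,
                                             replicate = sprintf("R%d", r),
                                             repIndex = r))
        }))
      } else {
        simulatePatchTruth(pp, nReplicates = ex$n_replicates, seed = pp@seed)
      }
      tc <- prevalenceTimeCourse(calls)
      tc$strain <- strain
      exoRows[[strain]] <- tc
    }
    exoTable <- do.call(rbind, exoRows)
    rownames(exoTable) <- NULL
    utils::write.csv(exoTable, file.path(outdir, "exocytosis_time_course.csv"),
                     row.names = FALSE)
  }

  ## --- chemotaxis study ---------------------------------------------------
  cx <- config$chemotaxis
  chemoTable <- NULL
  if (!is.null(cx)) {
    wpChem <- function(bias) {
      WalkParams(meanSpeed = 2.5, dt = cx$dt_s, nSteps = cx$n_steps,
                 turnSd = 0.6, stepCv = 0.3, biasStrength = bias,
                 targetMode = if (bias > 0) "point_source" else "none",
                 target = as.numeric(cx$source))
    }
    esChem <- simulateExperiment(
      list(gradient = wpChem(cx$bias_strength), buffer = wpChem(0)),
      nCells = cx$n_cells, nReplicates = cx$n_replicates,
      seed = childSeed(seed, 202L))
    dd <- vapply(trajectories(esChem), deltaDistanceToSource, numeric(1),
                 source = as.numeric(cx$source))
    pers <- vapply(trajectories(esChem), gradientPersistence, numeric(1))
    chemoCells <- data.frame(
      cell_id = vapply(trajectories(esChem), cellId, character(1)),
      condition = vapply(trajectories(esChem), slot, character(1),
                         "condition"),
      replicate = vapply(trajectories(esChem), slot, character(1),
                         "replicate"),
      delta_d = dd, persistence = pers)
    agg <- stats::aggregate(cbind(delta_d, persistence) ~ condition +
                              replicate, chemoCells, mean)
    tt <- tTestUnpaired(agg$delta_d[agg$condition == "gradient"],
                        agg$delta_d[agg$condition == "buffer"])
    chemoTable <- list(per_replicate = agg,
                       delta_d_p = tt$p, delta_d_t = tt$t)
    utils::write.csv(chemoCells, file.path(outdir, "chemotaxis_per_cell.csv"),
                     row.names = FALSE)
    utils::write.csv(agg, file.path(outdir, "chemotaxis_per_replicate.csv"),
                     row.names = FALSE)
  }

  nExcluded <- sum(cm$excluded)
  log <- c(log, sprintf("excluded stationary cells: %d", nExcluded))
  writeLines(log, file.path(outdir, "report.log"))

  summary <- list(
    seed = seed,
    shear_stress_pa = sigma,
    shear_stress_pa_nominal = round(sigma),
    n_trajectories = length(trajectories(es)),
    n_excluded = nExcluded,
    delta_x_mean = stats::setNames(
      lapply(conditions(es), function(cc) mean(repVals(cc, "delta_x"))),
      conditions(es)),
    speed_mean = stats::setNames(
      lapply(conditions(es), function(cc) mean(repVals(cc, "speed"))),
      conditions(es)),
    persistence_ratio = stats::setNames(as.list(ratios$persistence_ratio),
                                        ratios$strain),
    comparisons = comparisons,
    exocytosis = exoTable,
    chemotaxis_delta_d_p = if (is.null(chemoTable)) NULL else
      chemoTable$delta_d_p)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  invisible(summary)
}
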