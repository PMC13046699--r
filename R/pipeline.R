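#' Analyze one fixed-ratio drug pair
#'
#' The per-pair analysis chain: test the single-drug CRRCs for
#' parallelism, compute the matching additive prediction (point A for
#' parallel slopes, bounds A'/A'' otherwise), propagate SEM, fit the
#' mixture curve (point M), and call the interaction.
#'
#' @param fit_a,fit_b Single-drug `probit_fit`s.
#' @param mix_profile [inhibition_profile()] of the mixture on the
#'   total-concentration scale.
#' @param design A [fixed_ratio_design()].
#' @param est_a,est_b Optional `ic50_estimate`s overriding the
#'   fit-derived single-drug IC50s.
#' @param alpha Significance level for both the parallelism test and
#'   the interaction call.
#' @param tendency_k Tendency band width in additive SEMs.
#' @param n_mc,mc_seed Monte-Carlo settings for nonparallel SEM
#'   propagation.
#' @return A `pair_analysis`: `parallelism`, `prediction`, `mixture`,
#'   `result` (an `interaction_result`).
#' @export
analyze_pair <- function(fit_a, fit_b, mix_profile, design,
                         est_a = NULL, est_b = NULL,
                         alpha = 0.05, tendency_k = 1,
                         n_mc = 10000, mc_seed = 1) {
  if (is.null(est_a)) est_a <- ic50_linear(fit_a)
  if (is.null(est_b)) est_b <- ic50_linear(fit_b)
  est_a <- convert_estimate(est_a, design$unit)
  est_b <- convert_estimate(est_b, design$unit)
  par_test <- test_parallelism(fit_a, fit_b, alpha = alpha)
  pred <- if (par_test$verdict == "parallel") {
    additive_parallel(est_a, est_b, f = design$f, unit = design$unit)
  } else {
    additive_nonparallel(fit_a, fit_b, f = design$f,
                         est_a = est_a, est_b = est_b, unit = design$unit)
  }
  pred <- propagate_sem(pred, est_a, est_b, fit_a = fit_a, fit_b = fit_b,
                        n_mc = n_mc, seed = mc_seed)
  pred$drug_a <- design$drug_a
  pred$drug_b <- design$drug_b
  if (!is.na(est_a$cell_line)) pred$cell_line <- est_a$cell_line
  mix <- fit_mixture(mix_profile, design,
                     ic50_a = est_a$ic50, ic50_b = est_b$ic50)
  result <- interaction_call(mix, pred, alpha = alpha,
                             tendency_k = tendency_k)
  structure(list(parallelism = par_test, prediction = pred, mixture = mix,
                 result = result),
            class = "pair_analysis")
}

#' @export
print.pair_analysis <- function(x, ...) {
  print(x$result)
  invisible(x)
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates the complete workflow over a set of per-cell-line
#' synthetic configurations (see [scenario_study_defaults()]): simulate
#' single-drug and mixture plates, normalize to inhibition, fit the
#' log-probit curves, build additive predictions, call every pair's
#' interaction, and assemble polygonograms and the summary matrix.
#' Outputs are a pure function of `(configs, options, seed)`.
#'
#' @param configs Named list of [synthetic_config()]s, each carrying a
#'   `pairs` tibble (`drug_a`, `drug_b`, `f`).
#' @param seed Master integer seed; all plate seeds derive from it.
#' @param alpha Significance level.
#' @param tendency_k Tendency band width in additive SEMs.
#' @param n_mc Monte-Carlo draws for nonparallel SEM propagation.
#' @param holm Also report Holm-adjusted calls (default FALSE).
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV/JSON and a plain-text run log is emitted.
#' @return A `study_report`: `fits` tibble (drug x cell line IC50
#'   table), `results` (list of `interaction_result`), `calls` tibble,
#'   `polygonograms` (per cell line), `matrix` (`summary_matrix`),
#'   `seed`.
#' @export
run_pipeline <- function(configs, seed = 1, alpha = 0.05, tendency_k = 1,
                         n_mc = 10000, holm = FALSE, out_dir = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1)
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  log_msg("pipeline start: seed = ", seed, ", alpha = ", alpha,
          ", tendency_k = ", tendency_k, ", n_mc = ", n_mc)
  fits_rows <- list()
  results <- list()
  polys <- list()
  seed_counter <- 0L
  next_seed <- function() {
    seed_counter <<- seed_counter + 1L
    # double arithmetic, then reduce: derived seeds must stay < 2^31
    as.integer((as.numeric(seed) * 10000 + seed_counter) %% 2147483647)
  }
  for (cl in names(configs)) {
    cfg <- configs[[cl]]
    stopifnot(inherits(cfg, "synthetic_config"))
    log_msg("cell line ", cl, ": fitting ", nrow(cfg$drugs), " single drugs")
    fits <- list()
    ests <- list()
    for (i in seq_len(nrow(cfg$drugs))) {
      drug <- cfg$drugs$drug[[i]]
      sim <- simulate_single_drug_plate(cfg, drug, seed = next_seed())
      profile <- compute_inhibition(sim$raw, sim$layout)
      fit <- fit_log_probit(profile)
      fits[[drug]] <- fit
      ests[[drug]] <- ic50_linear(fit)
      fits_rows[[length(fits_rows) + 1L]] <- tibble::tibble(
        cell_line = cl, drug = drug,
        ic50 = ests[[drug]]$ic50, sem = ests[[drug]]$sem,
        unit = ests[[drug]]$unit,
        slope = fit$b, se_slope = fit$se_b,
        n_points = fit$n_points, n_window = fit$n_window,
        true_ic50 = cfg$drugs$ic50[[i]]
      )
    }
    pairs <- cfg$pairs
    if (is.null(pairs) || nrow(pairs) == 0) {
      log_msg("cell line ", cl, ": no pairs configured, fits only")
      next
    }
    cl_results <- list()
    for (j in seq_len(nrow(pairs))) {
      da <- pairs$drug_a[[j]]
      db <- pairs$drug_b[[j]]
      f <- pairs$f[[j]]
      unit <- drug_row(cfg, da)$unit
      design <- fixed_ratio_design(da, db, f = f, unit = unit)
      sim <- simulate_mixture_plate(cfg, da, db, f = f, seed = next_seed())
      mix_profile <- compute_inhibition(sim$raw, sim$layout)
      pa <- tryCatch(
        analyze_pair(fits[[da]], fits[[db]], mix_profile, design,
                     est_a = ests[[da]], est_b = ests[[db]],
                     alpha = alpha, tendency_k = tendency_k,
                     n_mc = n_mc, mc_seed = next_seed()),
        error = function(e) {
          stop("pair stage failed for ", da, "+", db, " on ", cl, ": ",
               conditionMessage(e), call. = FALSE)
        })
      log_msg("  ", da, "+", db, ": ", pa$parallelism$verdict, ", ",
              pa$result$label, " (p = ", signif(pa$result$p, 3), ")")
      cl_results[[j]] <- pa$result
    }
    results <- c(results, cl_results)
    polys[[cl]] <- build_polygonogram(cl_results, cell_line = cl)
  }
  fits_tab <- dplyr::bind_rows(fits_rows)
  calls <- if (length(results)) interaction_table(results) else tibble::tibble()
  mat <- if (length(results) && length(unique(calls$cell_line)) >= 1) {
    summarize_matrix(results, cell_lines = names(polys))
  }
  if (holm && length(results)) {
    adj <- holm_adjust_calls(results, alpha = alpha, tendency_k = tendency_k)
    calls$p_holm <- vapply(adj, function(r) r$p_holm, numeric(1))
    calls$label_holm <- vapply(adj, function(r) r$label, character(1))
  }
  log_msg("pipeline done: ", nrow(fits_tab), " fits, ", length(results),
          " interaction calls")
  report <- structure(
    list(fits = fits_tab, results = results, calls = calls,
         polygonograms = polys, matrix = mat, seed = seed,
         options = list(alpha = alpha, tendency_k = tendency_k, n_mc = n_mc,
                        holm = holm),
         log = log_lines),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed ", x$seed, ": ", nrow(x$fits),
      " single-drug fits, ", length(x$results), " interaction calls\n",
      sep = "")
  if (length(x$results)) {
    print(table(x$calls$label))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the fit table, the interaction-call table, per-cell-line
#' polygonogram edge tables, the summary matrix, and the run log —
#' every figure-ready quantity in machine-readable form.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$fits, "fits.csv")
  if (nrow(report$calls)) wr(report$calls, "interaction_calls.csv")
  for (cl in names(report$polygonograms)) {
    wr(report$polygonograms[[cl]]$edges,
       paste0("polygonogram_", gsub("[^A-Za-z0-9]", "_", cl), ".csv"))
  }
  if (!is.null(report$matrix)) {
    wr(report$matrix$grid, "summary_matrix_long.csv")
    wr(report$matrix$matrix, "summary_matrix.csv")
  }
  jsonlite::write_json(
    list(seed = report$seed, options = report$options,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("isobolr"))),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE)
  writeLines(report$log, file.path(out_dir, "run_log.txt"))
  invisible(c(paths, file.path(out_dir, c("run_metadata.json", "run_log.txt"))))
}

#' Isobologram coordinates and figure for one pair
#'
#' Builds the figure-ready geometry of an isobologram in component-dose
#' coordinates: single-drug IC50s on the axes with SEM bars, the
#' additivity line (parallel) or the two bounding power isoboles
#' (nonparallel, sampled at `n_curve` points), the additive point(s)
#' A or A'/A'', and the experimental mixture point M, each with SEM
#' bars along the mixture ray.
#'
#' @param result An `interaction_result` (supplies point M).
#' @param pred The matching `additive_prediction`.
#' @param mixture The `mixture_fit` (component decomposition of M).
#' @param verdict Optional parallelism verdict; an inconsistency with
#'   the prediction mode is an error.
#' @param n_curve Samples per nonparallel isobole curve (default 100).
#' @return List of class `isobologram`: `axes` tibble, `lines` tibble
#'   (`curve`, `a`, `b`), `points` tibble (A/A'/A''/M with SEM), and
#'   `plot` (ggplot).
#' @export
export_isobologram <- function(result, pred, mixture, verdict = NULL,
                               n_curve = 100) {
  stopifnot(inherits(result, "interaction_result"),
            inherits(pred, "additive_prediction"),
            inherits(mixture, "mixture_fit"))
  if (!is.null(verdict)) {
    expected <- if (verdict == "parallel") "parallel" else "nonparallel"
    if (pred$mode != expected) {
      stop("mode mismatch: prediction is ", pred$mode,
           " but parallelism verdict is ", verdict, call. = FALSE)
    }
  }
  ia <- pred$ic50_a
  ib <- pred$ic50_b
  axes <- tibble::tibble(
    drug = c(pred$drug_a, pred$drug_b),
    axis = c("a", "b"),
    ic50 = c(ia, ib)
  )
  if (pred$mode == "parallel") {
    lines <- tibble::tibble(curve = "additivity",
                            a = c(ia, 0), b = c(0, ib))
  } else {
    r <- pred$r
    a_seq <- seq(0, ia, length.out = n_curve)
    b_seq <- seq(0, ib, length.out = n_curve)
    lines <- dplyr::bind_rows(
      tibble::tibble(curve = "b-referenced",
                     a = a_seq, b = ib * (1 - (a_seq / ia)^r)),
      tibble::tibble(curve = "a-referenced",
                     a = ia * (1 - (b_seq / ib)^(1 / r)), b = b_seq)
    )
  }
  pt_rows <- lapply(names(pred$points), function(nm) {
    p <- pred$points[[nm]]
    label <- c(A = "A", A_prime = "A'", A_dprime = "A''")[[nm]]
    tibble::tibble(point = label, a = p$a, b = p$b, total = p$total,
                   sem = p$sem)
  })
  mshare <- mixture$components / sum(mixture$components)
  pts <- dplyr::bind_rows(
    dplyr::bind_rows(pt_rows),
    tibble::tibble(point = "M",
                   a = mixture$components[["a"]],
                   b = mixture$components[["b"]],
                   total = mixture$total, sem = mixture$sem)
  )
  # SEM bars run along the mixture ray: split each total SEM into
  # component offsets proportional to the point's own (a, b) shares
  pts$a_lo <- pts$a * (1 - pts$sem / pts$total)
  pts$a_hi <- pts$a * (1 + pts$sem / pts$total)
  pts$b_lo <- pts$b * (1 - pts$sem / pts$total)
  pts$b_hi <- pts$b * (1 + pts$sem / pts$total)
  plot <- ggplot2::ggplot() +
    ggplot2::geom_path(data = lines,
                       ggplot2::aes(.data$a, .data$b, group = .data$curve),
                       linetype = "dashed", color = "grey40") +
    ggplot2::geom_segment(data = pts,
                          ggplot2::aes(x = .data$a_lo, y = .data$b_lo,
                                       xend = .data$a_hi, yend = .data$b_hi),
                          color = "grey30") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$a, .data$b, shape = .data$point),
                        size = 3) +
    ggplot2::geom_point(data = axes,
                        ggplot2::aes(x = ifelse(.data$axis == "a", .data$ic50, 0),
                                     y = ifelse(.data$axis == "b", .data$ic50, 0)),
                        shape = 4, size = 3) +
    ggplot2::labs(
      x = paste0(pred$drug_a, " (", pred$unit, ")"),
      y = paste0(pred$drug_b, " (", pred$unit, ")"),
      title = paste0(pred$drug_a, " + ", pred$drug_b,
                     if (!is.na(result$cell_line))
                       paste0(" on ", result$cell_line),
                     " - ", result$label)) +
    ggplot2::theme_classic()
  structure(list(axes = axes, lines = lines, points = pts, plot = plot,
                 unit = pred$unit, mode = pred$mode),
            class = "isobologram")
}
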