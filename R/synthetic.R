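#' Configure a synthetic MTT study
#'
#' Defines the ground truth for simulated MTT plates: per-drug true
#' IC50s and probit slopes, concentration grids, replication, per-well
#' noise on the inhibition scale, the optical-density model for
#' control/blank wells, and the Loewe-interaction parameter `kappa`
#' applied to mixtures (`kappa = 1` exact additivity, `< 1` synergy,
#' `> 1` antagonism; the true mixture IC50 is `kappa` times the
#' parallel additive IC50).
#'
#' Defaults mirror a triplicate 96-well MTT experiment: 3 replicate
#' wells per concentration, 7 log-spaced concentrations spanning
#' IC50/16 to 16 x IC50 (guaranteeing points inside the 16-84% probit
#' window), 5 percentage points of Gaussian per-well noise, control
#' wells near OD 1.0 over a 0.08 blank.
#'
#' @param drugs Tibble (or data frame) with columns `drug`, `ic50`,
#'   `unit`, and optionally `slope` (default 2).
#' @param cell_line Cell-line tag.
#' @param replicates Wells per concentration (default 3).
#' @param n_conc Concentrations per grid (default 7).
#' @param grid_span Half-span of the log-spaced grid as a multiple of
#'   IC50 (default 16).
#' @param noise_sd Per-well Gaussian noise SD, percentage points of
#'   inhibition (default 5).
#' @param control_od,blank_od Mean optical densities of untreated
#'   controls and cell-free blanks (defaults 1.0, 0.08).
#' @param od_noise_sd OD noise SD for control/blank wells (default
#'   0.02).
#' @param n_control,n_blank Control and blank wells per plate
#'   (defaults 6, 3).
#' @param kappa True interaction parameter (> 0, default 1).
#' @param mixture_slope How the mixture CRRC slope is formed from the
#'   component slopes: `"weighted-mean"` (arithmetic, weighted by `f`;
#'   default) or a fixed number.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(drugs, cell_line = "synthetic",
                             replicates = 3, n_conc = 7, grid_span = 16,
                             noise_sd = 5, control_od = 1.0, blank_od = 0.08,
                             od_noise_sd = 0.02, n_control = 6, n_blank = 3,
                             kappa = 1, mixture_slope = "weighted-mean") {
  drugs <- tibble::as_tibble(drugs)
  stopifnot(all(c("drug", "ic50", "unit") %in% names(drugs)))
  if (is.null(drugs$slope)) drugs$slope <- 2
  stopifnot(all(drugs$ic50 > 0), all(drugs$slope > 0),
            replicates >= 1, noise_sd >= 0, kappa > 0,
            control_od > blank_od, n_control >= 3, n_blank >= 1)
  drugs$unit <- normalize_unit(drugs$unit)
  structure(
    list(drugs = drugs, cell_line = cell_line,
         replicates = replicates, n_conc = n_conc, grid_span = grid_span,
         noise_sd = noise_sd, control_od = control_od, blank_od = blank_od,
         od_noise_sd = od_noise_sd, n_control = n_control, n_blank = n_blank,
         kappa = kappa, mixture_slope = mixture_slope),
    class = "synthetic_config"
  )
}

drug_row <- function(cfg, drug) {
  i <- match(drug, cfg$drugs$drug)
  if (is.na(i)) stop("drug '", drug, "' not in config", call. = FALSE)
  cfg$drugs[i, ]
}

log_grid <- function(center, span, n) {
  10^seq(log10(center / span), log10(center * span), length.out = n)
}

# Shared plate builder: probit-shaped mean inhibition around (ic50, slope)
# on the given grid, Gaussian per-well noise on the inhibition scale,
# mapped back to OD through the control/blank model.
build_plate <- function(cfg, agent, unit, grid, ic50, slope, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mean_inh <- 100 * stats::pnorm(slope * (log10(grid) - log10(ic50)))
  if (all(mean_inh < 1) || all(mean_inh > 99)) {
    warning("uninformative design: concentration grid lies entirely ",
            "outside the (1%, 99%) response region", call. = FALSE)
  }
  rows <- list()
  wells <- character(0)
  well_id <- function(i) sprintf("W%02d", i)
  k <- 0
  od <- numeric(0)
  add_well <- function(role, agent = NA, conc = NA, unit = NA, rep = NA,
                       reading) {
    k <<- k + 1
    rows[[k]] <<- tibble::tibble(well = well_id(k), role = role,
                                 agent = agent, concentration = conc,
                                 unit = unit, replicate = rep)
    od <<- c(od, max(reading, 0))
  }
  for (i in seq_len(cfg$n_blank)) {
    add_well("blank",
             reading = cfg$blank_od + stats::rnorm(1, 0, cfg$od_noise_sd))
  }
  for (i in seq_len(cfg$n_control)) {
    add_well("control",
             reading = cfg$control_od + stats::rnorm(1, 0, cfg$od_noise_sd))
  }
  span_od <- cfg$control_od - cfg$blank_od
  for (ci in seq_along(grid)) {
    for (r in seq_len(cfg$replicates)) {
      inh <- mean_inh[ci] + stats::rnorm(1, 0, cfg$noise_sd)
      viab <- (100 - inh) / 100
      add_well("treated", agent = agent, conc = grid[ci], unit = unit,
               rep = r, reading = cfg$blank_od + span_od * viab)
    }
  }
  layout_df <- dplyr::bind_rows(rows)
  layout <- plate_layout(layout_df)
  raw <- read_plate(tibble::tibble(well = layout_df$well, od = od), layout,
                    cell_line = cfg$cell_line, assay_id = agent)
  list(raw = raw, layout = layout)
}

#' Simulate a single-drug MTT plate
#'
#' Mean inhibition at concentration `c` is
#' `100 * pnorm(slope * (log10(c) - log10(IC50)))`; per-well inhibition
#' adds Gaussian noise and is converted back to an optical density
#' through the control/blank model (truncated so OD >= 0).
#' Deterministic under `seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param drug Drug name present in `cfg$drugs`.
#' @param seed Integer seed.
#' @param grid Optional explicit concentration grid (default: the
#'   config's log-spaced grid around the true IC50).
#' @return List with `raw` (a `raw_plate`) and `layout`
#'   (a `plate_layout`).
#' @export
simulate_single_drug_plate <- function(cfg, drug, seed = 1, grid = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  d <- drug_row(cfg, drug)
  if (is.null(grid)) grid <- log_grid(d$ic50, cfg$grid_span, cfg$n_conc)
  build_plate(cfg, d$drug, d$unit, grid, d$ic50, d$slope, seed)
}

mixture_truth <- function(cfg, a, b, f, kappa) {
  # true additive total under parallel Loewe arithmetic, in a's unit
  ic50_b <- convert_conc(b$ic50, b$unit, a$unit)
  total_add <- f * a$ic50 + (1 - f) * ic50_b
  slope <- if (identical(cfg$mixture_slope, "weighted-mean")) {
    f * a$slope + (1 - f) * b$slope
  } else {
    as.numeric(cfg$mixture_slope)
  }
  list(ic50 = kappa * total_add, slope = slope, unit = a$unit,
       total_add = total_add)
}

#' Simulate a fixed-ratio mixture MTT plate
#'
#' The mixture responds as a probit curve in total concentration with
#' true `IC50 = kappa * (f * IC50_A + (1 - f) * IC50_B)` and slope
#' equal to the `f`-weighted mean of the component slopes. `kappa = 1`
#' encodes exact Loewe additivity, `kappa < 1` synergy, `kappa > 1`
#' antagonism.
#'
#' @param cfg A [synthetic_config()].
#' @param drug_a,drug_b Component drug names.
#' @param f Drug A's IC50-fraction share (default 0.5).
#' @param kappa Interaction parameter; default: the config's.
#' @param seed Integer seed.
#' @return List with `raw`, `layout`, and `truth` (true mixture IC50,
#'   slope, unit, and the parallel additive total).
#' @export
simulate_mixture_plate <- function(cfg, drug_a, drug_b, f = 0.5,
                                   kappa = cfg$kappa, seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"), kappa > 0, f > 0, f < 1)
  a <- drug_row(cfg, drug_a)
  b <- drug_row(cfg, drug_b)
  truth <- mixture_truth(cfg, a, b, f, kappa)
  grid <- log_grid(truth$ic50, cfg$grid_span, cfg$n_conc)
  agent <- paste0(drug_a, "+", drug_b)
  out <- build_plate(cfg, agent, truth$unit, grid, truth$ic50, truth$slope,
                     seed)
  out$truth <- truth
  out
}

#' Construct a sham self-combination
#'
#' The classical validity check for an isobolographic pipeline: "drug
#' A" and "drug B" are the same compound, with B relabelled at a
#' different unit scale (nM vs uM), so the true interaction is exact
#' additivity by construction and any synergy/antagonism call is a
#' false positive.
#'
#' @param cfg A [synthetic_config()].
#' @param drug Drug name in `cfg$drugs`.
#' @return A `synthetic_config` containing pseudo-drugs `<drug>.A`
#'   (original unit) and `<drug>.B` (same compound expressed in the
#'   other unit), identical slopes.
#' @export
sham_pair <- function(cfg, drug) {
  stopifnot(inherits(cfg, "synthetic_config"))
  d <- drug_row(cfg, drug)
  other <- if (d$unit == "uM") "nM" else "uM"
  drugs <- tibble::tibble(
    drug = paste0(d$drug, c(".A", ".B")),
    ic50 = c(d$ic50, convert_conc(d$ic50, d$unit, other)),
    unit = c(d$unit, other),
    slope = c(d$slope, d$slope)
  )
  cfg$drugs <- drugs
  cfg
}

#' Ground-truth configurations modelled on a published melanoma panel
#'
#' Returns one [synthetic_config()] per cell line of a four-line human
#' malignant melanoma panel (FM55P, A375, FM55M2, SK-MEL28) with five
#' cytostatics (cisplatin, docetaxel, mitoxantrone, vemurafenib,
#' selumetinib). True IC50s are set to published MTT-derived values so
#' simulated studies live on a realistic concentration scale
#' (docetaxel in nM, the others in uM); true probit slopes are not
#' published and default to 2.0 as a placeholder. All ten drug pairs
#' at `f = 0.5` are attached as the pair design.
#'
#' @param ... Overrides passed to [synthetic_config()] (e.g.
#'   `noise_sd`, `kappa`).
#' @return Named list of 4 `synthetic_config`s, each with a `pairs`
#'   tibble (`drug_a`, `drug_b`, `f`) attached.
#' @export
scenario_study_defaults <- function(...) {
  ref <- reference_ic50_table()
  lines <- unique(ref$cell_line)
  configs <- lapply(lines, function(cl) {
    d <- ref[ref$cell_line == cl, c("drug", "ic50", "unit")]
    d$slope <- 2
    cfg <- synthetic_config(d, cell_line = cl, ...)
    pairs <- t(utils::combn(d$drug, 2))
    cfg$pairs <- tibble::tibble(drug_a = pairs[, 1], drug_b = pairs[, 2],
                                f = 0.5)
    cfg
  })
  names(configs) <- lines
  configs
}

#' Published single-drug IC50 reference table
#'
#' MTT-derived IC50 +/- SEM of five cytostatics on four human melanoma
#' cell lines, as published; used as ground truth for the synthetic
#' scenarios and as worked-example input for the isobole arithmetic.
#' Docetaxel is in nM, all other drugs in uM.
#'
#' @return Tibble: `cell_line`, `drug`, `ic50`, `sem`, `unit`.
#' @export
reference_ic50_table <- function() {
  lines <- c("FM55P", "A375", "FM55M2", "SK-MEL28")
  make <- function(drug, unit, ic50, sem) {
    tibble::tibble(cell_line = lines, drug = drug, ic50 = ic50, sem = sem,
                   unit = unit)
  }
  dplyr::bind_rows(
    make("cisplatin", "uM", c(1.49, 1.29, 1.70, 3.30),
         c(0.30, 0.34, 0.30, 0.70)),
    make("docetaxel", "nM", c(1.27, 15.05, 2.06, 15.83),
         c(0.55, 3.27, 0.66, 9.05)),
    make("mitoxantrone", "uM", c(0.35, 0.04, 0.13, 1.74),
         c(0.10, 0.02, 0.02, 0.51)),
    make("vemurafenib", "uM", c(0.76, 6.07, 0.62, 0.25),
         c(0.26, 2.06, 0.27, 0.13)),
    make("selumetinib", "uM", c(0.10, 0.20, 0.22, 0.15),
         c(0.04, 0.07, 0.08, 0.07))
  )
}
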