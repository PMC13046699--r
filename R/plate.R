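#' Construct and validate a plate layout
#'
#' A plate layout maps wells of an MTT assay plate to their roles.
#' Blank wells contain medium without cells, control wells contain
#' untreated cells, and treated wells carry an agent (a single drug or
#' a fixed-ratio mixture) at a positive concentration with a replicate
#' index.
#'
#' @param df Data frame with columns `well`, `role` (one of
#'   `"blank"`, `"control"`, `"treated"`), and, for treated wells,
#'   `agent`, `concentration`, `unit` (`"nM"` or `"uM"`), `replicate`.
#' @param blank_value Optional explicit blank optical density used when
#'   the layout has no blank wells (e.g. `0` for pre-blanked readers).
#' @return A `plate_layout` object (a validated tibble with the
#'   `blank_value` attribute).
#' @export
plate_layout <- function(df, blank_value = NULL) {
  df <- tibble::as_tibble(df)
  required <- c("well", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("layout is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$well)) {
    dup <- unique(df$well[duplicated(df$well)])
    stop("duplicate well(s) in layout: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$role %in% c("blank", "control", "treated"))) {
    stop("layout roles must be one of blank/control/treated", call. = FALSE)
  }
  n_blank <- sum(df$role == "blank")
  if (n_blank == 0 && is.null(blank_value)) {
    stop("layout needs at least one blank well or an explicit blank_value",
         call. = FALSE)
  }
  if (sum(df$role == "control") < 3) {
    stop("layout needs at least 3 control wells", call. = FALSE)
  }
  treated <- df[df$role == "treated", , drop = FALSE]
  if (nrow(treated) > 0) {
    for (col in c("agent", "concentration", "unit", "replicate")) {
      if (is.null(treated[[col]]) || anyNA(treated[[col]])) {
        stop("treated wells must carry non-missing '", col, "'", call. = FALSE)
      }
    }
    if (any(treated$concentration <= 0)) {
      stop("treated concentrations must be > 0", call. = FALSE)
    }
    normalize_unit(treated$unit)
    dup_rep <- duplicated(treated[, c("agent", "concentration", "replicate")])
    if (any(dup_rep)) {
      stop("duplicate (agent, concentration, replicate) entries in layout",
           call. = FALSE)
    }
  }
  structure(df, class = c("plate_layout", class(df)),
            blank_value = blank_value)
}

#' Read raw optical densities against a layout
#'
#' Pairs a long-format table of optical-density readings (one row per
#' well) with a [plate_layout()], checking that every layout well has a
#' finite, non-negative reading.
#'
#' @param source A data frame with columns `well` and `od`, or a path
#'   to a CSV file with those columns.
#' @param layout A [plate_layout()].
#' @param cell_line,assay_id Optional plate metadata.
#' @return A `raw_plate` object: a tibble `(well, od)` carrying the
#'   layout and metadata as attributes.
#' @export
read_plate <- function(source, layout, cell_line = NA_character_,
                       assay_id = NA_character_) {
  stopifnot(inherits(layout, "plate_layout"))
  df <- if (is.character(source) && length(source) == 1) {
    tibble::as_tibble(utils::read.csv(source, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(source)
  }
  if (!all(c("well", "od") %in% names(df))) {
    stop("plate table must have columns 'well' and 'od'", call. = FALSE)
  }
  if (anyDuplicated(df$well)) {
    dup <- unique(df$well[duplicated(df$well)])
    stop("duplicate reading(s) for well(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(layout$well, df$well)
  if (length(absent) > 0) {
    stop("missing reading(s) for layout well(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- df[match(layout$well, df$well), c("well", "od")]
  if (anyNA(df$od) || any(!is.finite(df$od))) {
    stop("non-finite optical density reading(s)", call. = FALSE)
  }
  if (any(df$od < 0)) {
    bad <- df$well[df$od < 0]
    stop("negative optical density in well(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("raw_plate", class(df)),
            layout = layout, cell_line = cell_line, assay_id = assay_id)
}

#' @export
print.raw_plate <- function(x, ...) {
  cat("<raw_plate> ", nrow(x), " wells",
      if (!is.na(attr(x, "cell_line"))) paste0(" | cell line: ", attr(x, "cell_line")),
      "\n", sep = "")
  NextMethod()
}

plate_reference_levels <- function(raw, layout) {
  blank_value <- attr(layout, "blank_value")
  blank_mean <- if (any(layout$role == "blank")) {
    mean(raw$od[layout$role == "blank"])
  } else {
    blank_value
  }
  control_mean <- mean(raw$od[layout$role == "control"])
  if (control_mean <= blank_mean) {
    stop("degenerate plate: control mean OD (", signif(control_mean, 4),
         ") must exceed blank mean OD (", signif(blank_mean, 4), ")",
         call. = FALSE)
  }
  list(blank = blank_mean, control = control_mean)
}

#' Per-well viability fractions relative to plate controls
#' @keywords internal
plate_viability <- function(raw, layout) {
  ref <- plate_reference_levels(raw, layout)
  100 * (raw$od - ref$blank) / (ref$control - ref$blank)
}

#' Normalize a raw plate to percent inhibition of viability
#'
#' Per-well viability is `100 * (OD - mean blank OD) / (mean control OD
#' - mean blank OD)`; inhibition is `100 - viability`. Values falling
#' outside `[0, 100]` (noise below blank or above control) are clamped
#' with a warning so replicate counts stay balanced downstream.
#'
#' @param raw A `raw_plate` from [read_plate()].
#' @param layout The matching [plate_layout()]; defaults to the layout
#'   attached to `raw`.
#' @return One [inhibition_profile()] per agent when the plate carries
#'   several agents (a named list), or a single profile otherwise.
#' @export
compute_inhibition <- function(raw, layout = attr(raw, "layout")) {
  stopifnot(inherits(raw, "raw_plate"), inherits(layout, "plate_layout"))
  viability <- plate_viability(raw, layout)
  treated_idx <- which(layout$role == "treated")
  if (length(treated_idx) == 0) {
    stop("layout has no treated wells", call. = FALSE)
  }
  inhibition <- 100 - viability[treated_idx]
  n_clamped <- sum(inhibition < 0 | inhibition > 100)
  if (n_clamped > 0) {
    warning(n_clamped, " inhibition value(s) outside [0, 100] clamped",
            call. = FALSE)
    inhibition <- pmin(pmax(inhibition, 0), 100)
  }
  treated <- layout[treated_idx, , drop = FALSE]
  data <- tibble::tibble(
    agent = treated$agent,
    concentration = treated$concentration,
    unit = normalize_unit(treated$unit),
    replicate = treated$replicate,
    inhibition = inhibition
  )
  agents <- unique(data$agent)
  profiles <- lapply(agents, function(a) {
    d <- data[data$agent == a, , drop = FALSE]
    inhibition_profile(
      agent = a,
      cell_line = attr(raw, "cell_line"),
      unit = d$unit[[1]],
      data = d[, c("concentration", "replicate", "inhibition")]
    )
  })
  names(profiles) <- agents
  if (length(profiles) == 1) profiles[[1]] else profiles
}

#' Construct an inhibition profile
#'
#' The per-concentration replicate percent-inhibition record for one
#' agent (single drug or fixed-ratio mixture) on one cell line — the
#' input to the log-probit fit.
#'
#' @param agent Agent identifier.
#' @param cell_line Cell-line tag.
#' @param unit Concentration unit (`"nM"` or `"uM"`).
#' @param data Tibble with columns `concentration`, `replicate`,
#'   `inhibition` (percent, in `[0, 100]`).
#' @return An `inhibition_profile` object.
#' @export
inhibition_profile <- function(agent, cell_line, unit, data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration", "replicate", "inhibition") %in% names(data)))
  unit <- normalize_unit(unit)
  if (any(data$concentration <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(data$inhibition < 0 | data$inhibition > 100)) {
    stop("inhibition values must lie in [0, 100]", call. = FALSE)
  }
  if (length(unique(data$concentration)) < 2) {
    stop("an inhibition profile needs at least 2 distinct concentrations",
         call. = FALSE)
  }
  structure(
    list(agent = agent, cell_line = cell_line, unit = unit,
         data = data[order(data$concentration, data$replicate), ]),
    class = "inhibition_profile"
  )
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat("<inhibition_profile> ", x$agent,
      if (!is.na(x$cell_line)) paste0(" on ", x$cell_line),
      ": ", length(unique(x$data$concentration)), " concentrations (",
      x$unit, "), ", nrow(x$data), " wells\n", sep = "")
  invisible(x)
}

#' Per-concentration summary of an inhibition profile
#'
#' @param profile An [inhibition_profile()].
#' @return Tibble with `concentration`, `n`, `mean_inhibition`, `sem`.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "inhibition_profile"))
  d <- profile$data
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$concentration),
    n = dplyr::n(),
    mean_inhibition = mean(.data$inhibition),
    sem = stats::sd(.data$inhibition) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  out$sem[out$n < 2] <- NA_real_
  out
}

star_code <- function(p) {
  # strict inequalities at the conventional 0.05/0.01/0.001/0.0001 tiers
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' One-way ANOVA with Tukey post-hoc on plate viability
#'
#' Runs a one-way ANOVA over control and treated wells on the viability
#' scale, followed by Tukey's HSD comparing each concentration against
#' the untreated control, with the conventional four-tier star codes
#' (strict `p < 0.05 / 0.01 / 0.001 / 0.0001`).
#'
#' @param x A `raw_plate`, or a data frame with columns `group` and
#'   `viability` (one group may be named `"control"`; Tukey vs-control
#'   comparisons are only reported when it is present).
#' @param layout Matching [plate_layout()]; defaults to the one on `x`
#'   when `x` is a plate.
#' @param agent Agent to analyze when the plate has several (default:
#'   all).
#' @return A list of class `viability_stats`: `per_concentration`
#'   tibble (`group`, `concentration`, `n`, `mean_viability`, `sem`,
#'   `p_adj`, `stars`), omnibus `f`, `df`, `p`.
#' @export
viability_anova <- function(x, layout = attr(x, "layout"), agent = NULL) {
  if (inherits(x, "raw_plate")) {
    stopifnot(inherits(layout, "plate_layout"))
    viability <- plate_viability(x, layout)
    treated <- layout$role == "treated"
    if (!is.null(agent)) treated <- treated & layout$agent == agent
    keep <- layout$role == "control" | treated
    d <- tibble::tibble(
      group = ifelse(layout$role[keep] == "control", "control",
                     format(layout$concentration[keep], trim = TRUE)),
      concentration = ifelse(layout$role[keep] == "control", NA_real_,
                             layout$concentration[keep]),
      viability = viability[keep]
    )
  } else {
    d <- tibble::as_tibble(x)
    stopifnot(all(c("group", "viability") %in% names(d)))
    if (!"concentration" %in% names(d)) {
      d$concentration <- suppressWarnings(as.numeric(d$group))
    }
  }
  tab <- table(d$group)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs at least 2 replicates", call. = FALSE)
  within_var <- tapply(d$viability, d$group, stats::var)
  if (all(within_var == 0)) {
    stop("zero within-group variance: all replicates tie exactly; ",
         "ANOVA is undefined (add measurement noise or use an exact test)",
         call. = FALSE)
  }
  has_control <- "control" %in% d$group
  grp <- factor(d$group)
  if (has_control) grp <- stats::relevel(grp, ref = "control")
  fit <- stats::aov(d$viability ~ grp)
  an <- stats::anova(fit)

  per_conc <- dplyr::summarise(
    dplyr::group_by(d[d$group != "control", ], .data$group, .data$concentration),
    n = dplyr::n(),
    mean_viability = mean(.data$viability),
    sem = stats::sd(.data$viability) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  if (has_control) {
    tk <- stats::TukeyHSD(fit)$grp
    vs_control <- grepl("-control$", rownames(tk))
    tk_ctrl <- tk[vs_control, , drop = FALSE]
    conc_label <- sub("-control$", "", rownames(tk_ctrl))
    per_conc$p_adj <- tk_ctrl[match(per_conc$group, conc_label), "p adj"]
    per_conc$stars <- star_code(per_conc$p_adj)
  } else {
    per_conc$p_adj <- NA_real_
    per_conc$stars <- NA_character_
  }
  per_conc <- per_conc[order(per_conc$concentration), ]
  control <- if (has_control) {
    list(n = sum(d$group == "control"),
         mean_viability = mean(d$viability[d$group == "control"]),
         sem = stats::sd(d$viability[d$group == "control"]) /
           sqrt(sum(d$group == "control")))
  }
  structure(
    list(per_concentration = per_conc,
         f = an$`F value`[[1]],
         df = c(an$Df[[1]], an$Df[[2]]),
         p = an$`Pr(>F)`[[1]],
         control = control),
    class = "viability_stats"
  )
}

#' @export
print.viability_stats <- function(x, ...) {
  cat("<viability_stats> omnibus F(", x$df[1], ",", x$df[2], ") = ",
      signif(x$f, 4), ", p = ", signif(x$p, 3), "\n", sep = "")
  print(x$per_concentration)
  invisible(x)
}
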