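#' Fit the mixture concentration-response curve (point M)
#'
#' Fits the log-probit line to a fixed-ratio mixture profile whose
#' concentrations are total mixture concentrations along the design's
#' ray, and decomposes the experimental mixture IC50 into its component
#' doses using the design fractions.
#'
#' @param profile An [inhibition_profile()] of the mixture (total
#'   concentration scale).
#' @param design A [fixed_ratio_design()].
#' @param ic50_a,ic50_b Single-drug IC50s (in the design unit) used for
#'   the component split. If omitted the split is proportional to `f`
#'   on the total scale.
#' @return A `mixture_fit`: the underlying `probit_fit` and
#'   `ic50_estimate` plus `components = c(a, b)` summing to the total
#'   mixture IC50.
#' @export
fit_mixture <- function(profile, design, ic50_a = NULL, ic50_b = NULL) {
  stopifnot(inherits(profile, "inhibition_profile"),
            inherits(design, "fixed_ratio_design"))
  fit <- fit_log_probit(profile)
  est <- ic50_linear(fit)
  est <- convert_estimate(est, design$unit)
  f <- design$f
  if (!is.null(ic50_a) && !is.null(ic50_b)) {
    # along the ray the component shares follow the single-drug IC50s
    wa <- f * ic50_a
    wb <- (1 - f) * ic50_b
    share_a <- wa / (wa + wb)
  } else {
    share_a <- f
  }
  structure(
    list(fit = fit, estimate = est, design = design,
         total = est$ic50, sem = est$sem,
         components = c(a = share_a * est$ic50,
                        b = (1 - share_a) * est$ic50)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", x$design$drug_a, "+", x$design$drug_b,
      " (f = ", x$design$f, "): IC50mix = ", signif(x$total, 5), " +/- ",
      signif(x$sem, 4), " ", x$design$unit, "\n", sep = "")
  invisible(x)
}

#' Welch-corrected comparison of mixture vs additive IC50
#'
#' Unpaired t-test with Welch's correction comparing the experimentally
#' derived mixture IC50 against the theoretical additive IC50:
#' `t = (IC50_add - IC50_mix) / sqrt(SEM_add^2 + SEM_mix^2)` with
#' Satterthwaite degrees of freedom. Positive `t` means the mixture is
#' more potent than additivity predicts (the synergy direction).
#'
#' @param mix,add `ic50_estimate` objects carrying `n_effective`.
#' @return A list of class `welch_result`: `t`, `df`, `p`, `note`.
#' @export
welch_compare <- function(mix, add) {
  stopifnot(inherits(mix, "ic50_estimate"), inherits(add, "ic50_estimate"))
  mix <- convert_estimate(mix, add$unit)
  v_add <- add$sem^2
  v_mix <- mix$sem^2
  diff <- add$ic50 - mix$ic50
  note <- NULL
  if (v_add == 0 && v_mix == 0) {
    if (diff == 0) {
      t <- 0; df <- Inf; p <- 1
    } else {
      t <- sign(diff) * Inf; df <- Inf; p <- 0
      note <- "degenerate: both SEMs are zero with unequal IC50s"
    }
  } else {
    t <- diff / sqrt(v_add + v_mix)
    df <- (v_add + v_mix)^2 /
      (v_add^2 / (add$n_effective - 1) + v_mix^2 / (mix$n_effective - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, note = note), class = "welch_result")
}

#' Classify a drug-pair interaction
#'
#' Decision rule: a significant Welch test (`p < alpha`) with
#' interaction index `gamma = IC50_mix / IC50_add` below 1 is
#' synergistic, above 1 antagonistic. A non-significant comparison is
#' labelled a tendency when the experimental point falls outside
#' `IC50_add +/- tendency_k * SEM_add`, and additive otherwise. At
#' `gamma = 1` the direction is undefined, so the call is never
#' synergistic or antagonistic regardless of `p`.
#'
#' @param p Welch p-value.
#' @param gamma Interaction index `IC50_mix / IC50_add` (> 0).
#' @param ic50_mix,ic50_add IC50s in a common unit.
#' @param sem_add SEM of the additive IC50.
#' @param alpha Significance level (default 0.05).
#' @param tendency_k Multiple of `SEM_add` beyond which a
#'   non-significant deviation is called a tendency (default 1).
#' @return Character label: `"synergistic"`, `"tendency-to-synergy"`,
#'   `"additive"`, `"tendency-to-antagonism"`, or `"antagonistic"`.
#' @export
classify_interaction <- function(p, gamma, ic50_mix, ic50_add, sem_add,
                                 alpha = 0.05, tendency_k = 1) {
  stopifnot(p >= 0, p <= 1, gamma > 0)
  if (p < alpha && gamma < 1) return("synergistic")
  if (p < alpha && gamma > 1) return("antagonistic")
  # float tie-break: exactly coincident estimates are additive
  tol <- 1e-9 * ic50_add
  if (ic50_mix < ic50_add - tendency_k * sem_add - tol) {
    return("tendency-to-synergy")
  }
  if (ic50_mix > ic50_add + tendency_k * sem_add + tol) {
    return("tendency-to-antagonism")
  }
  "additive"
}

interaction_labels <- c("synergistic", "tendency-to-synergy", "additive",
                        "tendency-to-antagonism", "antagonistic")

#' Compare a mixture fit against an additive prediction
#'
#' Convenience wrapper producing the full interaction record for one
#' drug pair on one cell line: Welch test, interaction index, class
#' label and star code.
#'
#' @param mix A `mixture_fit` (or `ic50_estimate` of the mixture).
#' @param pred An `additive_prediction` with SEMs populated.
#' @param alpha,tendency_k See [classify_interaction()].
#' @return An `interaction_result` (a one-row tibble-backed record).
#' @export
interaction_call <- function(mix, pred, alpha = 0.05, tendency_k = 1) {
  mix_est <- if (inherits(mix, "mixture_fit")) mix$estimate else mix
  stopifnot(inherits(mix_est, "ic50_estimate"))
  add_est <- additive_estimate(pred)
  mix_est <- convert_estimate(mix_est, add_est$unit)
  w <- welch_compare(mix_est, add_est)
  gamma <- mix_est$ic50 / add_est$ic50
  label <- classify_interaction(w$p, gamma, mix_est$ic50, add_est$ic50,
                                add_est$sem, alpha = alpha,
                                tendency_k = tendency_k)
  structure(
    list(cell_line = pred$cell_line,
         drug_a = pred$drug_a, drug_b = pred$drug_b,
         f = pred$f, mode = pred$mode, unit = add_est$unit,
         ic50_mix = mix_est$ic50, sem_mix = mix_est$sem,
         n_mix = mix_est$n_effective,
         ic50_add = add_est$ic50, sem_add = add_est$sem,
         n_add = add_est$n_effective,
         t = w$t, df = w$df, p = w$p,
         gamma = gamma, label = label, stars = star_code(w$p)),
    class = "interaction_result"
  )
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result> ", x$drug_a, "+", x$drug_b,
      if (!is.na(x$cell_line)) paste0(" on ", x$cell_line), "\n",
      "  IC50mix = ", signif(x$ic50_mix, 4), " +/- ", signif(x$sem_mix, 3),
      " ", x$unit, "; IC50add = ", signif(x$ic50_add, 4), " +/- ",
      signif(x$sem_add, 3), " ", x$unit, "\n",
      "  t = ", signif(x$t, 4), ", df = ", signif(x$df, 3), ", p = ",
      signif(x$p, 3), ", gamma = ", signif(x$gamma, 4), " -> ", x$label,
      if (nzchar(x$stars)) paste0(" ", x$stars), "\n", sep = "")
  invisible(x)
}

#' Interaction results as a tidy tibble
#'
#' @param results A list of `interaction_result` objects.
#' @return A tibble, one row per pair x cell line.
#' @export
interaction_table <- function(results) {
  if (inherits(results, "interaction_result")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::as_tibble(unclass(r)[c(
      "cell_line", "drug_a", "drug_b", "f", "mode", "unit",
      "ic50_mix", "sem_mix", "ic50_add", "sem_add",
      "t", "df", "p", "gamma", "label", "stars")])
  }))
}

#' Holm adjustment across interaction calls
#'
#' The primary analysis applies no multiplicity correction across the
#' pair-by-cell-line comparisons; this helper re-runs the
#' classification with Holm-adjusted p-values for sensitivity analysis.
#'
#' @param results List of `interaction_result` objects.
#' @param alpha,tendency_k See [classify_interaction()].
#' @return The list with `p_holm` added and labels recomputed from it.
#' @export
holm_adjust_calls <- function(results, alpha = 0.05, tendency_k = 1) {
  p <- vapply(results, function(r) r$p, numeric(1))
  p_adj <- stats::p.adjust(p, method = "holm")
  Map(function(r, pa) {
    r$p_holm <- pa
    r$label <- classify_interaction(pa, r$gamma, r$ic50_mix, r$ic50_add,
                                    r$sem_add, alpha, tendency_k)
    r$stars <- star_code(pa)
    r
  }, results, p_adj)
}

label_style <- function(label) {
  style <- list(
    "synergistic" = c(color = "green", linetype = "solid"),
    "tendency-to-synergy" = c(color = "green", linetype = "dashed"),
    "additive" = c(color = "black", linetype = "solid"),
    "tendency-to-antagonism" = c(color = "red", linetype = "dashed"),
    "antagonistic" = c(color = "red", linetype = "solid")
  )
  style[[label]]
}

#' Build a polygonogram for one cell line
#'
#' A polygonogram is the complete graph over the analyzed drugs with
#' each edge styled by the interaction class of the pair: green solid
#' for synergy, green dashed for a tendency to synergy, black for
#' additivity, red dashed for a tendency to antagonism, red solid for
#' antagonism.
#'
#' @param results List of `interaction_result` objects for one cell
#'   line.
#' @param cell_line Cell-line tag (checked against the results when
#'   they carry one).
#' @return A `polygonogram`: `nodes` (drug tibble) and `edges` tibble
#'   with `drug_a`, `drug_b`, `label`, `color`, `linetype`.
#' @export
build_polygonogram <- function(results, cell_line = NA_character_) {
  if (inherits(results, "interaction_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  tab <- interaction_table(results)
  if (!is.na(cell_line)) {
    tab <- tab[is.na(tab$cell_line) | tab$cell_line == cell_line, ]
  }
  key <- paste(pmin(tab$drug_a, tab$drug_b), pmax(tab$drug_a, tab$drug_b))
  if (anyDuplicated(key)) {
    stop("duplicate drug pair(s) for one cell line: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  styles <- t(vapply(tab$label, label_style, c(color = "", linetype = "")))
  edges <- tibble::tibble(
    drug_a = tab$drug_a, drug_b = tab$drug_b, label = tab$label,
    color = unname(styles[, "color"]), linetype = unname(styles[, "linetype"])
  )
  drugs <- sort(unique(c(edges$drug_a, edges$drug_b)))
  structure(
    list(cell_line = cell_line,
         nodes = tibble::tibble(drug = drugs),
         edges = edges),
    class = "polygonogram"
  )
}

#' @export
print.polygonogram <- function(x, ...) {
  cat("<polygonogram>",
      if (!is.na(x$cell_line)) paste0(" ", x$cell_line), ": ",
      nrow(x$nodes), " drugs, ", nrow(x$edges), " pairs\n", sep = "")
  print(x$edges)
  invisible(x)
}

#' Plot a polygonogram
#'
#' Drugs on a circle, pair edges colored/dashed by interaction class.
#'
#' @param x A `polygonogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.polygonogram <- function(x, ...) {
  n <- nrow(x$nodes)
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  pos <- tibble::tibble(drug = x$nodes$drug, px = cos(theta), py = sin(theta))
  e <- dplyr::left_join(x$edges, pos, by = c(drug_a = "drug"))
  e <- dplyr::left_join(e, pos, by = c(drug_b = "drug"),
                        suffix = c("", "_end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$px, y = .data$py,
                   xend = .data$px_end, yend = .data$py_end),
      color = e$color, linetype = e$linetype, linewidth = 0.8) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$px, .data$py),
                        size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(1.15 * .data$px, 1.15 * .data$py,
                                    label = .data$drug)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(if (!is.na(x$cell_line)) x$cell_line else "")
}

label_to_code <- function(label) {
  switch(label,
         "synergistic" = "S",
         "tendency-to-synergy" = "S",
         "additive" = "0",
         "tendency-to-antagonism" = "A",
         "antagonistic" = "A",
         stop("unknown label: ", label, call. = FALSE))
}

#' Summarize interactions as a pair x cell-line code matrix
#'
#' Codes: `"S"` for synergy or a tendency to synergy, `"A"` for
#' antagonism or a tendency to antagonism, `"0"` for plain additivity.
#' Pairs with the same code in every cell line collapse to that single
#' code; mixed pairs keep per-line annotations.
#'
#' @param results List of `interaction_result` objects spanning the
#'   cell lines.
#' @param cell_lines Expected cell lines (default: those present);
#'   every pair must have one result per line.
#' @return A `summary_matrix`: long tibble `grid` (`pair`,
#'   `cell_line`, `label`, `code`), wide `matrix` tibble, and
#'   `collapsed` tibble with a single code or per-line annotation per
#'   pair.
#' @export
summarize_matrix <- function(results, cell_lines = NULL) {
  tab <- interaction_table(results)
  tab$pair <- paste(pmin(tab$drug_a, tab$drug_b),
                    pmax(tab$drug_a, tab$drug_b), sep = " + ")
  if (is.null(cell_lines)) cell_lines <- unique(tab$cell_line)
  missing <- vapply(unique(tab$pair), function(p) {
    paste(setdiff(cell_lines, tab$cell_line[tab$pair == p]), collapse = ",")
  }, character(1))
  if (any(nzchar(missing))) {
    gaps <- paste0(names(missing)[nzchar(missing)], " (",
                   missing[nzchar(missing)], ")")
    stop("missing cell line result(s) for: ", paste(gaps, collapse = "; "),
         call. = FALSE)
  }
  grid <- tibble::tibble(
    pair = tab$pair, cell_line = tab$cell_line, label = tab$label,
    code = vapply(tab$label, label_to_code, character(1))
  )
  wide <- tidyr::pivot_wider(grid[, c("pair", "cell_line", "code")],
                             names_from = "cell_line", values_from = "code")
  collapsed <- dplyr::bind_rows(lapply(split(grid, grid$pair), function(g) {
    uniform <- length(unique(g$code)) == 1
    tibble::tibble(
      pair = g$pair[[1]],
      code = if (uniform) g$code[[1]] else
        paste0(g$code, "(", g$cell_line, ")", collapse = " "),
      uniform = uniform
    )
  }))
  structure(list(grid = grid, matrix = wide, collapsed = collapsed,
                 cell_lines = cell_lines),
            class = "summary_matrix")
}

#' @export
print.summary_matrix <- function(x, ...) {
  cat("<summary_matrix> S = synergy or tendency to synergy, ",
      "A = antagonism direction, 0 = additive\n", sep = "")
  print(x$matrix)
  invisible(x)
}
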