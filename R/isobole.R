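#' Define a fixed-ratio combination design
#'
#' A fixed-ratio design specifies the mixture ray along which a drug
#' pair is co-administered. The ratio is expressed in IC50 fractions:
#' `f` is drug A's share of the IC50-normalized dose, so `f = 0.5`
#' encodes the classical 1:1 design in which each drug contributes an
#' equal fraction of its own IC50 (`a / IC50_A = b / IC50_B`).
#'
#' @param drug_a,drug_b Drug identifiers.
#' @param f Drug A's IC50-fraction share, in (0, 1). Default 0.5.
#' @param unit Common working unit for the ray.
#' @return A `fixed_ratio_design`.
#' @export
fixed_ratio_design <- function(drug_a, drug_b, f = 0.5, unit = "uM") {
  stopifnot(f > 0, f < 1)
  structure(
    list(drug_a = drug_a, drug_b = drug_b, f = f,
         unit = normalize_unit(unit)),
    class = "fixed_ratio_design"
  )
}

as_common_unit <- function(est_a, est_b, unit = NULL) {
  if (is.null(unit)) unit <- est_a$unit
  list(a = convert_estimate(est_a, unit), b = convert_estimate(est_b, unit),
       unit = unit)
}

#' Additive IC50 prediction for parallel curves
#'
#' Under Loewe additivity with parallel CRRCs the 50% isobole is the
#' straight segment between the single-drug IC50s, and the additive
#' mixture IC50 along the fixed-ratio ray is the IC50-fraction-weighted
#' sum `IC50_add = f * IC50_A + (1 - f) * IC50_B`, with variance
#' `f^2 * SEM_A^2 + (1 - f)^2 * SEM_B^2` (independent estimates).
#'
#' @param est_a,est_b `ic50_estimate` objects (converted to a common
#'   unit automatically).
#' @param f Drug A's IC50-fraction share (default 0.5, the 1:1 ratio).
#' @param unit Working unit; default: the unit of `est_a`.
#' @return An `additive_prediction` with `mode = "parallel"`: the point
#'   A (`total` +/- `sem`), its component decomposition `(a, b)`, and
#'   the ray parameter `s`.
#' @export
additive_parallel <- function(est_a, est_b, f = 0.5, unit = NULL) {
  stopifnot(inherits(est_a, "ic50_estimate"), inherits(est_b, "ic50_estimate"),
            f > 0, f < 1)
  cu <- as_common_unit(est_a, est_b, unit)
  total <- f * cu$a$ic50 + (1 - f) * cu$b$ic50
  sem <- sqrt(f^2 * cu$a$sem^2 + (1 - f)^2 * cu$b$sem^2)
  structure(
    list(mode = "parallel",
         f = f, unit = cu$unit,
         points = list(
           A = list(total = total, sem = sem,
                    a = f * cu$a$ic50, b = (1 - f) * cu$b$ic50, s = f)
         ),
         ic50_a = cu$a$ic50, ic50_b = cu$b$ic50,
         n_effective = min(cu$a$n_effective, cu$b$n_effective),
         drug_a = cu$a$agent, drug_b = cu$b$agent,
         cell_line = cu$a$cell_line),
    class = "additive_prediction"
  )
}

#' Solve the fixed-ratio / power-isobole intersection
#'
#' For the 1:1 IC50-fraction ray, intersecting the dose-equivalence
#' power isobole with slope ratio `r` reduces to finding the unique
#' `s` in (0, 1) with `s + s^r = 1`. The root is bracketed and solved
#' to absolute tolerance 1e-10.
#'
#' @param r Positive, finite slope ratio.
#' @return The ray parameter `s` in (0, 1).
#' @examples
#' solve_ray_fraction(1)  # 0.5
#' solve_ray_fraction(2)  # (sqrt(5) - 1) / 2
#' @export
solve_ray_fraction <- function(r) {
  if (!is.finite(r) || r <= 0) {
    stop("slope ratio r must be finite and > 0", call. = FALSE)
  }
  eps <- 1e-12
  g <- function(s) s + s^r - 1
  stats::uniroot(g, c(eps, 1 - eps), tol = 1e-12)$root
}

# General-f version: intersect the B-referenced power isobole
# b = IC50_B * (1 - (a / IC50_A)^r) with the ray a = 2 f s IC50_A,
# b = 2 (1 - f) s IC50_B; reduces to 2(1-f) s + (2 f s)^r = 1.
solve_ray_fraction_general <- function(r, f = 0.5) {
  if (!is.finite(r) || r <= 0) stop("slope ratio r must be finite and > 0",
                                    call. = FALSE)
  stopifnot(f > 0, f < 1)
  if (abs(f - 0.5) < 1e-15) return(solve_ray_fraction(r))
  eps <- 1e-12
  g <- function(s) 2 * (1 - f) * s + (2 * f * s)^r - 1
  upper <- min(1 / (2 * (1 - f)), 1 / (2 * f)) - eps
  stats::uniroot(g, c(eps, upper), tol = 1e-12)$root
}

#' Additive IC50 bounds for nonparallel curves
#'
#' When the two CRRCs are not parallel there is no single additivity
#' line. Dose-equivalence converts doses of one drug into equi-effective
#' doses of the other through the probit lines, which yields a curved
#' 50% isobole in each reference direction: with `r = bA / bB`, the
#' B-referenced isobole is `b = IC50_B * (1 - (a / IC50_A)^r)` and the
#' A-referenced one uses `1/r`. Intersecting each with the fixed-ratio
#' ray gives two additive totals bounding the additivity region; they
#' are reported as A' (lower) and A'' (upper). At `r = 1` both collapse
#' to the parallel point A.
#'
#' @param fit_a,fit_b `probit_fit` objects (slopes are taken from
#'   them); their IC50s are used unless `est_a`/`est_b` are supplied.
#' @param f Drug A's IC50-fraction share (default 0.5).
#' @param est_a,est_b Optional `ic50_estimate`s overriding the
#'   fit-derived IC50s (e.g. published values).
#' @param unit Working unit; default: drug A's unit.
#' @return An `additive_prediction` with `mode = "nonparallel"` and
#'   points `A_prime` (min) and `A_dprime` (max), each with components
#'   and ray parameter `s`.
#' @export
additive_nonparallel <- function(fit_a, fit_b, f = 0.5,
                                 est_a = NULL, est_b = NULL, unit = NULL) {
  stopifnot(inherits(fit_a, "probit_fit"), inherits(fit_b, "probit_fit"))
  if (fit_a$b <= 0 || fit_b$b <= 0) {
    stop("probit slopes must be positive", call. = FALSE)
  }
  if (is.null(est_a)) est_a <- ic50_linear(fit_a)
  if (is.null(est_b)) est_b <- ic50_linear(fit_b)
  r <- fit_a$b / fit_b$b
  if (r > 50 || r < 1 / 50) {
    warning("extreme slope ratio (", signif(r, 3),
            "): additivity bounds lie near the single-drug axes",
            call. = FALSE)
  }
  cu <- as_common_unit(est_a, est_b, unit)
  point_at <- function(s) {
    a <- 2 * f * s * cu$a$ic50
    b <- 2 * (1 - f) * s * cu$b$ic50
    list(total = a + b, sem = NA_real_, a = a, b = b, s = s)
  }
  s1 <- solve_ray_fraction_general(r, f)      # B-referenced isobole
  s2 <- solve_ray_fraction_general(1 / r, f)  # A-referenced isobole
  p1 <- point_at(s1)
  p2 <- point_at(s2)
  if (p1$total <= p2$total) {
    pts <- list(A_prime = p1, A_dprime = p2)
  } else {
    pts <- list(A_prime = p2, A_dprime = p1)
  }
  structure(
    list(mode = "nonparallel",
         f = f, unit = cu$unit, r = r,
         points = pts,
         ic50_a = cu$a$ic50, ic50_b = cu$b$ic50,
         n_effective = min(cu$a$n_effective, cu$b$n_effective),
         drug_a = cu$a$agent, drug_b = cu$b$agent,
         cell_line = cu$a$cell_line),
    class = "additive_prediction"
  )
}

#' @export
print.additive_prediction <- function(x, ...) {
  cat("<additive_prediction> mode: ", x$mode, ", f = ", x$f, "\n", sep = "")
  for (nm in names(x$points)) {
    p <- x$points[[nm]]
    cat("  ", nm, ": total = ", signif(p$total, 5), " ", x$unit,
        if (!is.na(p$sem)) paste0(" +/- ", signif(p$sem, 5)),
        "  (a = ", signif(p$a, 4), ", b = ", signif(p$b, 4),
        ", s = ", signif(p$s, 5), ")\n", sep = "")
  }
  invisible(x)
}

#' Propagate IC50 uncertainty into the additive prediction
#'
#' Parallel mode: the analytic variance formula of
#' [additive_parallel()]. Nonparallel mode: seeded Monte Carlo — the
#' component IC50s (and slopes, when their standard errors are
#' supplied) are drawn from independent normals truncated at zero
#' (redrawn, not clamped), the additive points are recomputed for each
#' draw, and the sample SD is reported as the SEM of each point.
#'
#' @param pred An `additive_prediction`.
#' @param est_a,est_b `ic50_estimate`s for the components.
#' @param fit_a,fit_b Optional `probit_fit`s supplying slope SEs for
#'   nonparallel Monte Carlo.
#' @param n_mc Number of Monte Carlo draws (>= 100; default 10000).
#' @param seed Integer seed.
#' @return The prediction with `sem` filled in for every point.
#' @export
propagate_sem <- function(pred, est_a, est_b, fit_a = NULL, fit_b = NULL,
                          n_mc = 10000, seed = 1) {
  stopifnot(inherits(pred, "additive_prediction"))
  if (n_mc < 100) stop("n_mc must be >= 100", call. = FALSE)
  cu <- as_common_unit(est_a, est_b, pred$unit)
  f <- pred$f
  if (pred$mode == "parallel") {
    pred$points$A$sem <- sqrt(f^2 * cu$a$sem^2 + (1 - f)^2 * cu$b$sem^2)
    return(pred)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rtruncnorm_pos <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    while (any(bad <- out <= 0)) {
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    out
  }
  ic_a <- rtruncnorm_pos(n_mc, cu$a$ic50, cu$a$sem)
  ic_b <- rtruncnorm_pos(n_mc, cu$b$ic50, cu$b$sem)
  slopes_sampled <- !is.null(fit_a) && !is.null(fit_b) &&
    (fit_a$se_b > 0 || fit_b$se_b > 0)
  mean_comb <- f * ic_a + (1 - f) * ic_b
  if (slopes_sampled) {
    b_a <- rtruncnorm_pos(n_mc, fit_a$b, fit_a$se_b)
    b_b <- rtruncnorm_pos(n_mc, fit_b$b, fit_b$se_b)
    r <- b_a / b_b
    totals_low <- numeric(n_mc)
    totals_high <- numeric(n_mc)
    for (i in seq_len(n_mc)) {
      s1 <- solve_ray_fraction_general(r[i], f)
      s2 <- solve_ray_fraction_general(1 / r[i], f)
      t1 <- 2 * s1 * mean_comb[i]
      t2 <- 2 * s2 * mean_comb[i]
      totals_low[i] <- min(t1, t2)
      totals_high[i] <- max(t1, t2)
    }
  } else {
    # fixed slope ratio: the ray fractions are constants
    s1 <- solve_ray_fraction_general(pred$r, f)
    s2 <- solve_ray_fraction_general(1 / pred$r, f)
    t1 <- 2 * s1 * mean_comb
    t2 <- 2 * s2 * mean_comb
    totals_low <- pmin(t1, t2)
    totals_high <- pmax(t1, t2)
  }
  pred$points$A_prime$sem <- stats::sd(totals_low)
  pred$points$A_dprime$sem <- stats::sd(totals_high)
  pred$mc <- list(n_mc = n_mc, seed = seed,
                  slopes_sampled = !is.null(fit_a) && !is.null(fit_b))
  pred
}

#' Additive prediction as an IC50 estimate for Welch comparison
#'
#' Collapses an `additive_prediction` to a single `ic50_estimate`
#' comparable to the experimental mixture IC50: the point A for
#' parallel mode; for nonparallel mode the midpoint of A'/A'' with the
#' half-width of the bound interval folded into the SEM (in quadrature),
#' so that genuinely ambiguous additivity widens the test.
#'
#' @param pred An `additive_prediction` with SEMs populated.
#' @return An `ic50_estimate`.
#' @export
additive_estimate <- function(pred) {
  stopifnot(inherits(pred, "additive_prediction"))
  if (pred$mode == "parallel") {
    p <- pred$points$A
    sem <- p$sem
    total <- p$total
  } else {
    lo <- pred$points$A_prime
    hi <- pred$points$A_dprime
    total <- (lo$total + hi$total) / 2
    half <- (hi$total - lo$total) / 2
    base <- mean(c(lo$sem, hi$sem), na.rm = TRUE)
    if (!is.finite(base)) base <- 0
    sem <- sqrt(base^2 + half^2)
  }
  if (!is.finite(sem)) {
    stop("additive prediction has no SEM: run propagate_sem() first",
         call. = FALSE)
  }
  ic50_estimate(total, sem, pred$unit, n_effective = max(pred$n_effective, 2),
                agent = paste0(pred$drug_a, "+", pred$drug_b, " (additive)"),
                cell_line = pred$cell_line)
}
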