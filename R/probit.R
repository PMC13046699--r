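#' Fit a log-probit concentration-response line
#'
#' The concentration-response relationship curve (CRRC) is modelled as
#' `probit(inhibition fraction) = b * (log10(c) - mu)`, i.e. a straight
#' line in probit units versus log10 concentration with slope `b` and
#' 50%-crossing `mu = log10(IC50)`. Per-concentration mean inhibition
#' fractions are probit-transformed and regressed on log10
#' concentration by least squares weighted by replicate count.
#'
#' Concentrations whose mean inhibition lies outside `[0.5%, 99.5%]`
#' are excluded before the transform (the probit is undefined at 0/1
#' and unreliable just inside, mirroring the classical exclusion of
#' extreme responses).
#' In the tradition of probit analysis the regression uses working
#' weights that downweight extreme responses, where the probit
#' transform amplifies noise: for plate noise of roughly constant
#' variance on the inhibition scale, `Var(probit(p_hat))` scales as
#' `1 / (n * dnorm(probit(p))^2)`, so each concentration gets weight
#' `n * dnorm(probit(p_hat))^2`.
#'
#' @param profile An [inhibition_profile()].
#' @return A `probit_fit`: `agent`, `cell_line`, `unit`, slope `b` with
#'   `se_b`, `mu = log10(IC50)` with `se_mu`, intercept covariance
#'   terms, `n_points` (concentrations used), `n_window`
#'   (concentrations with mean inhibition strictly inside 16-84%, the
#'   probit +/-1 window used as the effective n downstream),
#'   `residual_se`, and character `flags`.
#' @export
fit_log_probit <- function(profile) {
  stopifnot(inherits(profile, "inhibition_profile"))
  s <- profile_summary(profile)
  frac <- s$mean_inhibition / 100
  usable <- frac >= 0.005 & frac <= 0.995
  s <- s[usable, , drop = FALSE]
  frac <- frac[usable]
  if (nrow(s) < 2) {
    stop("log-probit fit needs >= 2 concentrations with mean inhibition ",
         "inside [0.5%, 99.5%]", call. = FALSE)
  }
  flags <- character(0)
  if (all(frac < 0.5) || all(frac > 0.5)) {
    flags <- c(flags, "extrapolated IC50")
    warning("all usable mean responses on one side of 50%: IC50 is ",
            "extrapolated", call. = FALSE)
  }
  x <- log10(s$concentration)
  y <- stats::qnorm(frac)
  w <- s$n * stats::dnorm(y)^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  a <- cf[[1]]
  b <- cf[[2]]
  if (!is.finite(b) || b <= 0) {
    stop("fitted probit slope is not positive: profile is not consistent ",
         "with an inhibitor", call. = FALSE)
  }
  n_points <- nrow(s)
  if (n_points > 2) {
    # summary.lm warns on numerically perfect fits (noiseless profiles);
    # the zero covariance it returns is exactly what we want there
    vc <- suppressWarnings(stats::vcov(fit))
  } else {
    # two points determine the line exactly; no residual df
    vc <- matrix(0, 2, 2)
    flags <- c(flags, "saturated fit (2 points): standard errors unavailable")
  }
  mu <- -a / b
  # delta method for mu = -a/b
  grad <- c(-1 / b, a / b^2)
  var_mu <- drop(t(grad) %*% vc %*% grad)
  in_window <- s$mean_inhibition > 16 & s$mean_inhibition < 84
  n_window <- sum(in_window)
  # Litchfield-Wilcoxon N': subjects (wells) tested at the doses whose
  # responses fall in the 16-84% window, the effective n downstream
  n_window_wells <- sum(s$n[in_window])
  structure(
    list(agent = profile$agent, cell_line = profile$cell_line,
         unit = profile$unit,
         b = b, se_b = sqrt(vc[2, 2]),
         mu = mu, se_mu = sqrt(max(var_mu, 0)),
         intercept = a, se_intercept = sqrt(vc[1, 1]),
         cov_ab = vc[1, 2],
         n_points = n_points, n_window = n_window,
         n_window_wells = n_window_wells,
         residual_se = if (n_points > 2)
           suppressWarnings(summary(fit)$sigma) else 0,
         flags = flags),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("<probit_fit> ", x$agent,
      if (!is.na(x$cell_line)) paste0(" on ", x$cell_line), "\n",
      "  slope b = ", signif(x$b, 4), " +/- ", signif(x$se_b, 3),
      " probit / log10(", x$unit, ")\n",
      "  IC50 = ", signif(10^x$mu, 4), " ", x$unit,
      " (mu = ", signif(x$mu, 4), " +/- ", signif(x$se_mu, 3), ")\n",
      "  n_points = ", x$n_points, ", n_window = ", x$n_window, "\n",
      sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Linear-scale IC50 with delta-method SEM
#'
#' Back-transforms a probit fit to the concentration scale:
#' `IC50 = 10^mu` and `SEM = ln(10) * IC50 * SE(mu)` (first-order delta
#' method on the log10 scale). The effective sample size carried to
#' downstream Welch comparisons follows the Litchfield-Wilcoxon N'
#' convention: the number of wells at concentrations whose mean
#' response lies inside the 16-84% window (probit +/-1), floored at 2.
#'
#' @param fit A `probit_fit`.
#' @return An `ic50_estimate`: `agent`, `cell_line`, `ic50`, `sem`,
#'   `unit`, `n_effective`, `flags`.
#' @export
ic50_linear <- function(fit) {
  stopifnot(inherits(fit, "probit_fit"))
  ic50 <- 10^fit$mu
  structure(
    list(agent = fit$agent, cell_line = fit$cell_line,
         ic50 = ic50, sem = log(10) * ic50 * fit$se_mu,
         unit = fit$unit,
         n_effective = max(fit$n_window_wells, 2),
         flags = fit$flags),
    class = "ic50_estimate"
  )
}

#' Construct an IC50 estimate directly
#'
#' Useful for entering published IC50 +/- SEM values (e.g. reference
#' tables) into the isobole arithmetic without refitting.
#'
#' @param ic50 Median inhibitory concentration (> 0).
#' @param sem Standard error of the mean (>= 0).
#' @param unit `"nM"` or `"uM"`.
#' @param n_effective Effective n for Welch degrees of freedom (>= 2).
#' @param agent,cell_line Optional labels.
#' @return An `ic50_estimate`.
#' @export
ic50_estimate <- function(ic50, sem, unit, n_effective = 2,
                          agent = NA_character_, cell_line = NA_character_) {
  stopifnot(ic50 > 0, sem >= 0, n_effective >= 2)
  structure(
    list(agent = agent, cell_line = cell_line,
         ic50 = ic50, sem = sem, unit = normalize_unit(unit),
         n_effective = n_effective, flags = character(0)),
    class = "ic50_estimate"
  )
}

#' @export
print.ic50_estimate <- function(x, ...) {
  cat("<ic50_estimate> ", if (!is.na(x$agent)) paste0(x$agent, ": "),
      signif(x$ic50, 4), " +/- ", signif(x$sem, 4), " ", x$unit,
      " (n_eff = ", x$n_effective, ")\n", sep = "")
  invisible(x)
}

#' Convert an IC50 estimate to another unit
#' @param est An `ic50_estimate`.
#' @param to Target unit.
#' @return The estimate expressed in `to`.
#' @export
convert_estimate <- function(est, to) {
  stopifnot(inherits(est, "ic50_estimate"))
  to <- normalize_unit(to)
  est$ic50 <- convert_conc(est$ic50, est$unit, to)
  est$sem <- convert_conc(est$sem, est$unit, to)
  est$unit <- to
  est
}

#' Test two probit fits for parallelism
#'
#' Equal CRRC slopes justify the single straight additivity line; a
#' significant slope difference replaces it with lower/upper additivity
#' bounds. The test statistic is
#' `t = (bA - bB) / sqrt(SE_bA^2 + SE_bB^2)` with Welch-Satterthwaite
#' degrees of freedom built from the component regression dfs
#' (`n_points - 2` each).
#'
#' @param fit_a,fit_b `probit_fit` objects.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A `parallelism_result`: `slope_diff`, `se_diff`, `t`, `df`,
#'   `p`, `verdict` (`"parallel"` / `"nonparallel"`), `note`.
#' @export
test_parallelism <- function(fit_a, fit_b, alpha = 0.05) {
  stopifnot(inherits(fit_a, "probit_fit"), inherits(fit_b, "probit_fit"))
  diff <- fit_a$b - fit_b$b
  va <- fit_a$se_b^2
  vb <- fit_b$se_b^2
  note <- NULL
  if (va == 0 && vb == 0) {
    if (diff == 0) {
      t <- 0; df <- Inf; p <- 1
    } else {
      t <- sign(diff) * Inf; df <- Inf; p <- 0
      note <- "degenerate: both slope SEs are zero with unequal slopes"
    }
  } else {
    t <- diff / sqrt(va + vb)
    dfa <- max(fit_a$n_points - 2, 1)
    dfb <- max(fit_b$n_points - 2, 1)
    df <- (va + vb)^2 / (va^2 / dfa + vb^2 / dfb)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(
    list(slope_diff = diff, se_diff = sqrt(va + vb),
         t = t, df = df, p = p,
         verdict = if (p < alpha) "nonparallel" else "parallel",
         alpha = alpha, note = note),
    class = "parallelism_result"
  )
}

#' @export
print.parallelism_result <- function(x, ...) {
  cat("<parallelism_result> t = ", signif(x$t, 4), ", df = ",
      signif(x$df, 4), ", p = ", signif(x$p, 3), " -> ", x$verdict, "\n",
      sep = "")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
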