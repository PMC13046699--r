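# Shared fixtures: small plates and simulation wrappers built in code.

# A plate whose treated wells sit exactly on a probit line (no noise),
# via the synthetic generator with all noise switched off.
noiseless_config <- function(ic50 = 2, slope = 2, unit = "uM", ...) {
  synthetic_config(
    data.frame(drug = "drugX", ic50 = ic50, unit = unit, slope = slope),
    noise_sd = 0, od_noise_sd = 0, ...
  )
}

# Profile with means placed exactly at given inhibition fractions.
exact_profile <- function(conc, frac, reps = 1, unit = "uM",
                          agent = "drugX") {
  data <- do.call(rbind, lapply(seq_along(conc), function(i) {
    data.frame(concentration = conc[i], replicate = seq_len(reps),
               inhibition = 100 * frac[i])
  }))
  inhibition_profile(agent, NA_character_, unit, data)
}

# Tiny hand-built plate: 3 blanks (0.10), 6 controls (1.10), treated
# wells at given ODs.
hand_plate <- function(treated_od, conc = seq_along(treated_od),
                       agent = "drugX", unit = "uM",
                       blank = 0.10, control = 1.10) {
  n_t <- length(treated_od)
  layout <- plate_layout(data.frame(
    well = sprintf("W%02d", seq_len(3 + 6 + n_t)),
    role = c(rep("blank", 3), rep("control", 6), rep("treated", n_t)),
    agent = c(rep(NA, 9), rep(agent, n_t)),
    concentration = c(rep(NA, 9), conc),
    unit = c(rep(NA, 9), rep(unit, n_t)),
    replicate = c(rep(NA, 9), seq_len(n_t))
  ))
  raw <- read_plate(
    data.frame(well = layout$well,
               od = c(rep(blank, 3), rep(control, 6), treated_od)),
    layout)
  list(raw = raw, layout = layout)
}

# One full sham self-combination analysis; returns the interaction
# result and the parallelism verdict.
run_sham_analysis <- function(seed, kappa = 1, noise_sd = 5, n_mc = 1000,
                              od_noise_sd = if (noise_sd == 0) 0 else 0.02) {
  base <- data.frame(drug = "d", ic50 = 2, unit = "uM", slope = 2)
  cfg <- sham_pair(synthetic_config(base, noise_sd = noise_sd, kappa = kappa,
                                    od_noise_sd = od_noise_sd),
                   "d")
  sim_a <- simulate_single_drug_plate(cfg, "d.A", seed = seed * 10 + 1)
  sim_b <- simulate_single_drug_plate(cfg, "d.B", seed = seed * 10 + 2)
  fit_a <- fit_log_probit(compute_inhibition(sim_a$raw, sim_a$layout))
  fit_b <- fit_log_probit(compute_inhibition(sim_b$raw, sim_b$layout))
  design <- fixed_ratio_design("d.A", "d.B", unit = "uM")
  sim_m <- simulate_mixture_plate(cfg, "d.A", "d.B", seed = seed * 10 + 3,
                                  kappa = kappa)
  mix_prof <- compute_inhibition(sim_m$raw, sim_m$layout)
  analyze_pair(fit_a, fit_b, mix_prof, design,
               est_a = ic50_linear(fit_a), est_b = ic50_linear(fit_b),
               n_mc = n_mc, mc_seed = seed * 10 + 4)
}

# Independent brute-force oracle for the weighted LS probit objective:
# coarse grid over the full (b, mu) box, then a fine 1e-3 grid around
# the coarse optimum (the objective is smooth and unimodal in the box).
grid_search_probit <- function(profile, step = 1e-3,
                               b_range = c(0.1, 10), mu_range = c(-3, 3)) {
  s <- profile_summary(profile)
  frac <- s$mean_inhibition / 100
  keep <- frac >= 0.005 & frac <= 0.995
  s <- s[keep, ]
  frac <- frac[keep]
  x <- log10(s$concentration)
  y <- qnorm(frac)
  w <- s$n * dnorm(y)^2
  obj <- function(b, mu) {
    vapply(seq_along(b), function(i) {
      sum(w * (y - b[i] * (x - mu[i]))^2)
    }, numeric(1))
  }
  search <- function(bs, mus) {
    g <- expand.grid(b = bs, mu = mus)
    g[which.min(obj(g$b, g$mu)), ]
  }
  coarse <- search(seq(b_range[1], b_range[2], by = 0.05),
                   seq(mu_range[1], mu_range[2], by = 0.05))
  fine <- search(
    seq(max(b_range[1], coarse$b - 0.1), min(b_range[2], coarse$b + 0.1),
        by = step),
    seq(max(mu_range[1], coarse$mu - 0.1), min(mu_range[2], coarse$mu + 0.1),
        by = step))
  list(b = fine$b, mu = fine$mu)
}
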