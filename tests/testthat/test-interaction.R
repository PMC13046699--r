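test_that("Welch comparison matches its closed form", {
  add <- ic50_estimate(1.0, 0.1, "uM", n_effective = 4)
  mix <- ic50_estimate(0.5, 0.1, "uM", n_effective = 4)
  w <- welch_compare(mix, add)
  expect_equal(w$t, 0.5 / sqrt(0.02), tolerance = 1e-6) # 3.5355
  expect_equal(w$df, 6, tolerance = 1e-9)
  expect_equal(w$p, 2 * pt(-abs(w$t), 6), tolerance = 1e-12)
  expect_equal(w$p, 0.0122, tolerance = 1e-2)

  # identity
  w0 <- welch_compare(add, add)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # antisymmetry in the roles
  w_swap <- welch_compare(add, mix)
  expect_equal(w_swap$t, -w$t)
  expect_equal(w_swap$p, w$p)

  # degenerate zero-SEM cases
  z1 <- ic50_estimate(1, 0, "uM")
  z2 <- ic50_estimate(2, 0, "uM")
  expect_equal(welch_compare(z1, z1)$p, 1)
  dg <- welch_compare(z1, z2)
  expect_equal(dg$p, 0)
  expect_match(dg$note, "degenerate")

  # unit mismatch is resolved by conversion before comparing
  mix_nm <- ic50_estimate(500, 100, "nM", n_effective = 4)
  w_nm <- welch_compare(mix_nm, add)
  expect_equal(w_nm$t, w$t, tolerance = 1e-12)
})

test_that("interaction classification follows the decision rule", {
  cls <- classify_interaction
  expect_equal(cls(0.003, 0.6, 0.6, 1.0, 0.1), "synergistic")
  expect_equal(cls(0.003, 1.5, 1.5, 1.0, 0.1), "antagonistic")
  expect_equal(cls(0.40, 0.95, 0.95, 1.0, 0.1), "additive")
  expect_equal(cls(0.20, 1.15, 1.15, 1.0, 0.1), "tendency-to-antagonism")
  expect_equal(cls(0.20, 0.8, 0.8, 1.0, 0.1), "tendency-to-synergy")
  # gamma = 1 is never synergistic/antagonistic, whatever p
  expect_equal(cls(1e-8, 1, 1, 1, 0.1), "additive")
  # widening the tendency band turns a tendency into additive
  expect_equal(cls(0.20, 1.15, 1.15, 1.0, 0.1, tendency_k = 2), "additive")

  # monotone in p at fixed synergy direction: shrinking p never moves
  # the call away from synergistic
  ranks <- c("synergistic" = 3, "tendency-to-synergy" = 2, "additive" = 1)
  labels <- vapply(c(0.5, 0.2, 0.06, 0.04, 0.001),
                   function(p) cls(p, 0.7, 0.7, 1.0, 0.2), character(1))
  expect_true(all(diff(ranks[labels]) >= 0))
})

test_that("mixture fit decomposes the total IC50 along the ray", {
  # noiseless mixture: exact total IC50
  prof <- exact_profile(c(0.25, 1, 4), pnorm(c(-1.2, 0, 1.2)),
                        agent = "a+b")
  design <- fixed_ratio_design("a", "b", f = 0.5, unit = "uM")
  mf <- fit_mixture(prof, design, ic50_a = 1.0, ic50_b = 0.6)
  expect_equal(mf$total, 1, tolerance = 1e-9)
  expect_equal(sum(mf$components), mf$total, tolerance = 1e-12)
  # component shares follow the single-drug IC50s: a gets 1.0/1.6
  expect_equal(mf$components[["a"]] / mf$total, 1 / 1.6, tolerance = 1e-9)

  # without single-drug IC50s the split is proportional to f
  mf2 <- fit_mixture(prof, design)
  expect_equal(mf2$components[["a"]], 0.5 * mf2$total)
})

test_that("interaction_call assembles a consistent record", {
  ea <- ic50_estimate(1.0, 0.08, "uM", n_effective = 9, agent = "a")
  eb <- ic50_estimate(0.6, 0.05, "uM", n_effective = 9, agent = "b")
  pred <- additive_parallel(ea, eb)
  pred <- propagate_sem(pred, ea, eb)
  pred$drug_a <- "a"; pred$drug_b <- "b"
  mix <- ic50_estimate(0.35, 0.04, "uM", n_effective = 9, agent = "a+b")
  res <- interaction_call(mix, pred)
  expect_s3_class(res, "interaction_result")
  expect_equal(res$gamma, 0.35 / 0.8, tolerance = 1e-12)
  expect_equal(res$label, "synergistic")
  expect_gt(res$t, 0) # mixture more potent: synergy direction positive
  tab <- interaction_table(res)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$label, "synergistic")
})

test_that("polygonogram builds styled complete graphs", {
  mk_res <- function(a, b, label, cl = "L1") {
    structure(list(cell_line = cl, drug_a = a, drug_b = b, f = 0.5,
                   mode = "parallel", unit = "uM",
                   ic50_mix = 1, sem_mix = 0.1, n_mix = 9,
                   ic50_add = 1, sem_add = 0.1, n_add = 9,
                   t = 0, df = 8, p = 0.5, gamma = 1,
                   label = label, stars = ""),
              class = "interaction_result")
  }
  drugs <- letters[1:5]
  pairs <- t(combn(drugs, 2))
  labels <- rep(c("synergistic", "additive", "tendency-to-antagonism",
                  "tendency-to-synergy", "antagonistic"), 2)
  results <- lapply(seq_len(nrow(pairs)), function(i) {
    mk_res(pairs[i, 1], pairs[i, 2], labels[i])
  })
  pg <- build_polygonogram(results, cell_line = "L1")
  expect_equal(nrow(pg$nodes), 5)
  expect_equal(nrow(pg$edges), 10) # complete K5
  # style map
  style <- unique(pg$edges[, c("label", "color", "linetype")])
  expect_equal(style$color[style$label == "synergistic"], "green")
  expect_equal(style$linetype[style$label == "synergistic"], "solid")
  expect_equal(style$color[style$label == "tendency-to-synergy"], "green")
  expect_equal(style$linetype[style$label == "tendency-to-synergy"], "dashed")
  expect_equal(style$color[style$label == "additive"], "black")
  expect_equal(style$color[style$label == "tendency-to-antagonism"], "red")
  expect_equal(style$linetype[style$label == "tendency-to-antagonism"],
               "dashed")
  expect_equal(style$color[style$label == "antagonistic"], "red")

  # single pair
  pg1 <- build_polygonogram(list(mk_res("a", "b", "additive")))
  expect_equal(nrow(pg1$nodes), 2)
  expect_equal(pg1$edges$color, "black")

  # duplicate pair errors
  expect_error(
    build_polygonogram(list(mk_res("a", "b", "additive"),
                            mk_res("b", "a", "additive"))),
    "duplicate")

  p <- plot(pg)
  expect_s3_class(p, "ggplot")
})

test_that("summary matrix codes round-trip with the label classes", {
  mk_res <- function(a, b, label, cl) {
    structure(list(cell_line = cl, drug_a = a, drug_b = b, f = 0.5,
                   mode = "parallel", unit = "uM",
                   ic50_mix = 1, sem_mix = 0.1, n_mix = 9,
                   ic50_add = 1, sem_add = 0.1, n_add = 9,
                   t = 0, df = 8, p = 0.5, gamma = 1,
                   label = label, stars = ""),
              class = "interaction_result")
  }
  lines <- c("L1", "L2", "L3", "L4")
  results <- c(
    # synergy in 3 lines + tendency in 1 -> uniform "S"
    lapply(1:4, function(i) mk_res("a", "b",
      if (i < 4) "synergistic" else "tendency-to-synergy", lines[i])),
    # additive everywhere -> "0"
    lapply(1:4, function(i) mk_res("a", "c", "additive", lines[i])),
    # mixed: tendency-to-antagonism in 2, additive in 2
    lapply(1:4, function(i) mk_res("b", "c",
      if (i <= 2) "tendency-to-antagonism" else "additive", lines[i]))
  )
  sm <- summarize_matrix(results, cell_lines = lines)
  expect_equal(nrow(sm$grid), 12)
  ab <- sm$collapsed[sm$collapsed$pair == "a + b", ]
  expect_true(ab$uniform)
  expect_equal(ab$code, "S")
  ac <- sm$collapsed[sm$collapsed$pair == "a + c", ]
  expect_equal(ac$code, "0")
  bc <- sm$collapsed[sm$collapsed$pair == "b + c", ]
  expect_false(bc$uniform)
  expect_match(bc$code, "A\\(L1\\)")
  expect_match(bc$code, "0\\(L3\\)")

  # label -> code -> label-class round trip
  code_of <- isobolr:::label_to_code
  class_of_code <- list(S = c("synergistic", "tendency-to-synergy"),
                        A = c("tendency-to-antagonism", "antagonistic"),
                        "0" = "additive")
  for (lab in c("synergistic", "tendency-to-synergy", "additive",
                "tendency-to-antagonism", "antagonistic")) {
    expect_true(lab %in% class_of_code[[code_of(lab)]])
  }

  # missing cell line is reported
  expect_error(summarize_matrix(results[1:3], cell_lines = lines),
               "missing cell line")
})

test_that("Holm adjustment is available but off by default", {
  mk_res <- function(p, gamma) {
    structure(list(cell_line = "L1", drug_a = "a", drug_b = "b", f = 0.5,
                   mode = "parallel", unit = "uM",
                   ic50_mix = gamma, sem_mix = 0.01, n_mix = 9,
                   ic50_add = 1, sem_add = 0.01, n_add = 9,
                   t = 2, df = 8, p = p, gamma = gamma,
                   label = "synergistic", stars = ""),
              class = "interaction_result")
  }
  res <- list(mk_res(0.01, 0.7), mk_res(0.04, 0.8), mk_res(0.3, 0.9))
  adj <- holm_adjust_calls(res)
  expect_equal(vapply(adj, function(r) r$p_holm, numeric(1)),
               p.adjust(c(0.01, 0.04, 0.3), "holm"))
  # the p = 0.04 call loses significance under Holm
  expect_equal(adj[[2]]$label, "tendency-to-synergy")
})
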