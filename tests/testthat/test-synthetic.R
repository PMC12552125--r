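test_that("templates satisfy the cell-type ordering constraints", {
  tpl <- make_templates()
  expect_setequal(names(tpl), c("iNeuron", "iAstrocyte", "iMicroglia"))
  f <- sapply(tpl, `[[`, "fractions")
  expect_equal(unname(colSums(f)), rep(1, 3), tolerance = 1e-12)

  n <- f[, "iNeuron"]; a <- f[, "iAstrocyte"]; m <- f[, "iMicroglia"]
  # astrocyte-max CE; microglia SM > astrocyte SM > neuron SM
  expect_true(a["CE"] > n["CE"] && a["CE"] > m["CE"])
  expect_true(m["SM"] > a["SM"] && a["SM"] > n["SM"])
  # PC + PE dominate every template
  for (ct in colnames(f)) {
    top2 <- sort(f[, ct], decreasing = TRUE)[1:2]
    expect_setequal(names(top2), c("PC", "PE"))
  }
  # neuron-max CER/LPC/LPE; microglia-max TG/FFA; astrocyte-max DG;
  # PS high in microglia and astrocytes
  for (cl in c("CER", "LPC", "LPE")) {
    expect_true(n[cl] > a[cl] && n[cl] > m[cl], label = cl)
  }
  for (cl in c("TG", "FFA")) {
    expect_true(m[cl] > a[cl] && m[cl] > n[cl], label = cl)
  }
  expect_true(a["DG"] > n["DG"] && a["DG"] > m["DG"])
  expect_true(min(m["PS"], a["PS"]) > n["PS"])

  # roster: >= 1000 species over the 16-class registry, weights sum to 1
  r <- tpl$iNeuron$roster
  expect_gt(nrow(r), 1000)
  expect_setequal(unique(r$class), lipid_class_registry()$code)
  w <- tapply(r$weight, r$class, sum)
  expect_equal(as.vector(w), rep(1, 16), tolerance = 1e-12)
  expect_false(anyDuplicated(r$species) > 0)

  # thinning keeps determinism and renormalizes
  small <- make_templates(species_per_class = 5)[["iNeuron"]]$roster
  expect_true(all(table(small$class) <= 5))
  expect_equal(as.vector(tapply(small$weight, small$class, sum)),
               rep(1, 16), tolerance = 1e-12)
})

test_that("effect specs encode the documented directions", {
  eff <- make_effects()
  tpl <- make_templates(species_per_class = 10)[["iAstrocyte"]]
  r <- tpl$roster
  m_apoe <- lipotyper:::effect_multipliers(eff$apoe4, r)
  expect_true(all(m_apoe[r$class == "CE"] > 1))
  expect_true(all(m_apoe[r$class == "SM"] < 1))
  expect_true(all(m_apoe[r$class == "TG" & r$db <= 1] > 1))
  expect_true(all(m_apoe[r$class == "TG" & r$db > 1 & r$db <= 5] == 1))

  m_re <- lipotyper:::effect_multipliers(eff$reactive, r)
  expect_true(all(m_re[r$class %in% c("CE", "TG")] < 1))
  expect_true(all(m_re[r$class %in% phospholipid_classes() & r$db <= 1] > 1))
  expect_true(all(m_re[r$class %in% c("LCER", "HCER")] > 1))

  null_eff <- effect_spec("null", list(list(class = "CE", multiplier = 1)))
  expect_true(all(lipotyper:::effect_multipliers(null_eff, r) == 1))
  expect_error(effect_spec("bad", list(list(class = "CE", multiplier = -1))))
})

test_that("simulation is seed-deterministic and structurally complete", {
  tpl <- fast_template()
  d1 <- simulate_dataset(tpl, simulation_design(), seed = 123)
  d2 <- simulate_dataset(tpl, simulation_design(), seed = 123)
  expect_identical(d1$concentrations, d2$concentrations)
  d3 <- simulate_dataset(tpl, simulation_design(), seed = 124)
  expect_false(identical(d1$concentrations, d3$concentrations))

  expect_gte(sum(d1$samples$sample_type == "blank"), 2L)
  expect_gte(sum(d1$samples$sample_type == "qc"), 1L)
  bio <- d1$samples[d1$samples$sample_type == "biological", ]
  expect_setequal(unique(bio$replicate_id), paste0("exp", 1:3))
  man <- attr(d1, "manifest")
  expect_match(man$generator, "synthetic")
  expect_equal(man$seed, 123L)

  expect_error(simulation_design(groups = character()),
               class = "design_error")
  expect_error(simulation_design(n_per_group = 2, n_experiments = 3),
               class = "design_error")
  expect_error(simulate_dataset(tpl, simulation_design(),
                                effects = list(nope = make_effects()$apoe4),
                                seed = 1),
               class = "design_error")
})

test_that("zero noise with null effects reproduces template fractions", {
  tpl <- fast_template(noise_cv = 0)
  ds <- simulate_dataset(tpl, simulation_design(groups = "g", n_per_group = 2,
                                                n_experiments = 1),
                         seed = 1, low_fraction = 0, groupwise_fraction = 0,
                         missing_rate = 0)
  pr <- class_totals(ds)
  bio <- names(sample_groups(ds))
  for (s in bio) {
    expect_equal(pr$percent[names(tpl$fractions), s],
                 100 * tpl$fractions, tolerance = 1e-9)
  }
})

test_that("default generator exercises every filter verdict", {
  ds <- simulate_dataset(make_templates()[["iAstrocyte"]],
                         simulation_design(), seed = 2024)
  rep <- apply_blank_filter(ds)$report
  tot <- attr(rep, "totals")
  expect_gte(tot["reintroduced"], 1)
  expect_gte(tot["removed"], 1)
  expect_gte(tot["retained"] / sum(tot), 0.8)
})

test_that("injected CE multiplier is recovered as class log2FC", {
  # scaled-down Monte Carlo (20 seeds here; the acceptance suite runs more)
  tpl <- fast_template(species_per_class = 10)
  eff <- list(case = effect_spec("ce_up",
                                 list(list(class = "CE", multiplier = 1.5))))
  fc <- vapply(1:20, function(s) {
    ds <- simulate_dataset(tpl, simulation_design(n_per_group = 9),
                           effects = eff, seed = s, groupwise_fraction = 0)
    filtered <- apply_blank_filter(ds)$dataset
    pr <- class_totals(filtered)
    grp <- sample_groups(filtered)
    unname(log2_fold_change(pr$percent[, names(grp)], grp, "control",
                            "per-group", case_group = "case")["CE"])
  }, numeric(1))
  expect_lt(abs(mean(fc) - log2(1.5)), 0.15)
})
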