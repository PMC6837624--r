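tiny_cfg <- function(...) {
  ea_config(pop_size = 24, generations = 4, seed = 5, ...)
}

test_that("population initialization is reproducible and box-respecting", {
  spec <- synth_spec(family_exemplars()$NASP$params, 0.1)$spec
  cfg <- tiny_cfg()
  set.seed(cfg$seed)
  p1 <- initialize_population(spec, cfg, 24)
  set.seed(cfg$seed)
  p2 <- initialize_population(spec, cfg, 24)
  expect_identical(p1, p2)
  box <- default_class_boxes()$NASP
  for (g in p1) {
    expect_length(g, 9)
    expect_true(all(g >= box[, 1] - 1e-9 & g <= box[, 2] + 1e-9))
  }
})

test_that("initialization cycles through the boxes of all target classes", {
  spec <- phenotype_spec("two-class", list(
    pattern_target(0.4, "PSTUT"), pattern_target(0.6, "ASP.")))
  cfg <- tiny_cfg()
  set.seed(1)
  pop <- initialize_population(spec, cfg, 40)
  aspbox <- default_class_boxes()$ASP
  pstbox <- default_class_boxes()$PSTUT
  in_box <- function(g, b) all(g >= b[, 1] - 1e-9 & g <= b[, 2] + 1e-9)
  n_pst <- sum(vapply(pop, in_box, logical(1), pstbox))
  n_asp <- sum(vapply(pop, in_box, logical(1), aspbox))
  expect_gte(n_pst, 15)
  expect_gte(n_asp, 15)
})

test_that("a point initialization box degenerates to jittered copies", {
  spec <- synth_spec(family_exemplars()$NASP$params, 0.1)$spec
  boxes <- default_class_boxes()
  boxes$NASP[, 2] <- boxes$NASP[, 1]   # zero-volume box
  cfg <- tiny_cfg(boxes = boxes)
  set.seed(2)
  pop <- initialize_population(spec, cfg, 6)
  for (g in pop) expect_equal(g, pop[[1]])
})

test_that("identical spec, config and seed reproduce the fit exactly", {
  ss <- synth_spec(family_exemplars()$PSTUT$params, 0.3,
                   features = c("fsl", "pss"))
  f1 <- fit_phenotype(ss$spec, tiny_cfg())
  f2 <- fit_phenotype(ss$spec, tiny_cfg())
  expect_equal(f1$log, f2$log)
  expect_equal(f1$n_accepted, f2$n_accepted)
  expect_equal(f1$best_error, f2$best_error)
  if (f1$n_accepted > 0)
    expect_equal(tidy(f1), tidy(f2))
})

test_that("best error never increases across generations (elitism)", {
  ss <- synth_spec(family_exemplars()$NASP$params, 0.1)
  fit <- fit_phenotype(ss$spec, ea_config(pop_size = 30, generations = 8,
                                          seed = 2, stop_after = Inf))
  expect_true(all(diff(fit$log$best) <= 0))
})

test_that("acceptance demands class match, not merely a small error", {
  ex <- family_exemplars()$NASP
  ss <- synth_spec(ex$params, 0.1)
  expect_true(accept_model(ex$params, ss$spec))
  # same features but the wrong class target: rejected
  spec_wrong <- phenotype_spec("wrong-class", list(
    pattern_target(0.1, "ASP.",
                   features = ss$spec$patterns[[1]]$features)))
  expect_false(accept_model(ex$params, spec_wrong))
  # class match but one feature far outside tolerance: rejected
  feats <- ss$spec$patterns[[1]]$features
  feats$n_isis <- feats$n_isis + 3L
  spec_off <- phenotype_spec("off-count", list(
    pattern_target(0.1, "NASP", features = feats)))
  expect_false(accept_model(ex$params, spec_off))
})

test_that("every accepted model re-verifies from scratch", {
  ss <- synth_spec(family_exemplars()$NASP$params, 0.1)
  fit <- fit_phenotype(ss$spec, ea_config(pop_size = 60, generations = 20,
                                          seed = 4, stop_after = 2))
  expect_gt(fit$n_accepted, 0)
  for (a in fit$accepted)
    expect_true(accept_model(a$model, ss$spec, a$currents_pA))
})

test_that("the genome round-trips through decode for multi-compartment", {
  spec <- phenotype_spec("mc", list(pattern_target(0.15, "NASP")),
                         n_compartments = 2)
  g <- c(unlist(rs_params()),
         unlist(izhi_params(50, 0.35, -60, -30, 35, -45, 0.03, 0, 40))[
           c("C", "k", "Vt", "Vpeak", "Vmin", "a", "b", "d")], 25, 0.4)
  dec <- izhifit:::decode_genome(unname(g), spec)
  expect_equal(n_compartments(dec$model), 2)
  expect_equal(dec$model$edges$G, 25)
  expect_equal(dec$model$compartments$dend1$Vr, -60)
})

test_that("unknown stimulus amplitudes are searched inside their bracket", {
  spec <- phenotype_spec("unknown-amp", list(
    pattern_target(NA, "D.NASP", bracket_nA = c(0.07, 0.17))))
  lay <- izhifit:::genome_layout(spec)
  expect_equal(lay$n_genes, 10)
  cfg <- tiny_cfg()
  set.seed(3)
  pop <- initialize_population(spec, cfg, 10)
  amps <- vapply(pop, function(g)
    izhifit:::decode_genome(g, spec)$currents_pA, numeric(1))
  expect_true(all(amps >= 70 & amps <= 170))
  # repair clamps stray amplitude genes back into the bracket
  g <- pop[[1]]
  g[10] <- 500
  expect_equal(izhifit:::repair_genome(g, spec)[10], 170)
})

test_that("glance and autoplot summarise a fit", {
  ss <- synth_spec(family_exemplars()$NASP$params, 0.1)
  fit <- fit_phenotype(ss$spec, tiny_cfg())
  gl <- glance(fit)
  expect_equal(gl$seed, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})
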