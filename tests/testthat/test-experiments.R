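test_that("the unperturbed control reads 100% of basal everywhere", {
  ex <- run_source_decomposition(ref_model(), ref_params_cached())
  ctrl <- ex$readouts[ex$readouts$perturbation == "unperturbed control", ]
  expect_equal(ctrl$pct_of_basal, c(100, 100), tolerance = 1e-8)
})

test_that("knockdown dose response is monotone between control and knockout", {
  mod <- ref_model()
  p <- ref_params_cached()
  basal <- ref_basal()
  lvl <- vapply(c(1, 0.75, 0.5, 0.25, 0), function(s) {
    spec <- perturbation(enzyme_scales = c(PIP5KI = s))
    ss <- find_steady_state(mod, apply_perturbation(p, spec, mod),
                            x0 = basal$abundances)
    unname(ss$abundances["45"] / basal$abundances["45"])
  }, numeric(1))
  expect_true(all(diff(lvl) < 0))
  expect_equal(lvl[1], 1, tolerance = 1e-8)
})

test_that("PI(5)P channelling raises PI(4,5)P2 monotonically with PI(3)P influx", {
  ex <- run_pi5p_channeling(ref_model(), ref_params_cached(),
                            scale_v3 = c(1, 10, 25, 50))
  r45 <- ex$readouts[ex$readouts$species == "45", ]
  expect_true(all(diff(r45$pct_of_basal) > 0))
})

test_that("the siRNA panel classifies ENaC direction from PI(4,5)P2", {
  ex <- run_sirna_panel(ref_model(), ref_params_cached())
  ro <- ex$readouts[ex$readouts$species == "45", ]
  dir_of <- function(label_part) ro$enac_prediction[grepl(label_part, ro$perturbation)]
  expect_equal(dir_of("PIP5KI knockout"), "down")
  expect_equal(dir_of("PI4K knockout"), "down")
  expect_equal(dir_of("PI3KI knockout"), "unchanged")
  # PI3KII loss barely moves PI(4,5)P2 but wipes out PI(3,4)P2
  r34 <- ex$readouts[ex$readouts$species == "34", ]
  expect_lt(r34$pct_of_basal[grepl("PI3KII", r34$perturbation)], 15)
})

test_that("membrane polarity configurations separate the PI(3,4,5)P3 pool", {
  ap <- run_membrane_polarity(ref_model(), ref_params_cached(),
                              "apical", "slow")
  bl <- run_membrane_polarity(ref_model(), ref_params_cached(),
                              "basolateral", "slow")
  pip3 <- function(ex) ex$readouts$abundance[ex$readouts$species == "345"]
  expect_lt(pip3(ap), 10)
  expect_gt(pip3(bl), 500)
  # fast hydrolysis locks the membrane in a low-PI(3,4,5)P3 state even
  # after a deep PTEN knockdown
  fast_kd <- run_membrane_polarity(ref_model(), ref_params_cached(),
                                   "apical", "fast", pten_knockdown = 0.9833)
  pip2 <- fast_kd$readouts$pct_of_basal[fast_kd$readouts$species == "45"]
  expect_equal(pip2, 100, tolerance = 10)
})

test_that("experiment panels produce tidy CSV output", {
  dir <- tempfile()
  out <- reproduce_panel("golgi_pi4p", ref_model(), ref_params_cached(), dir = dir)
  f <- file.path(dir, "reproduce_golgi_pi4p.csv")
  expect_true(file.exists(f))
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_setequal(unique(back$species), c(4, 45))
  # the Golgi PI(4)P influx moves PI(4)P strongly but PI(4,5)P2 barely
  v4 <- back[back$species == 4, ]
  v45 <- back[back$species == 45, ]
  expect_gt(diff(range(v4$pct_of_basal)), 3 * diff(range(v45$pct_of_basal)))
})
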