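test_that("single-component compositions return that component's properties", {
  tab <- component_property_table()
  for (comp_name in rownames(tab)) {
    x <- stats::setNames(as.list(as.numeric(rownames(tab) == comp_name)),
                         rownames(tab))
    comp <- do.call(composition, x)
    expect_equal(estimate_density(comp), tab[comp_name, "rho"])
    expect_equal(estimate_heat_capacity(comp), tab[comp_name, "cp"])
    eps <- volume_fractions(comp)
    expect_equal(unname(eps[comp_name]), 1)
    for (g in c(0, 0.3, 1))
      expect_equal(estimate_thermal_conductivity(comp, g = g),
                   tab[comp_name, "k"])
  }
})

test_that("mixture rules match hand-evaluated two-component cases", {
  tab <- component_property_table()
  tab["water", "rho"] <- 1000; tab["fat", "rho"] <- 920
  comp <- composition(water = 0.5, fat = 0.5)
  expect_equal(estimate_density(comp, tab), 1 / (0.5 / 1000 + 0.5 / 920),
               tolerance = 1e-12)
  expect_equal(round(estimate_density(comp, tab), 2), 958.33)

  tab2 <- component_property_table()
  tab2["water", "cp"] <- 4180; tab2["protein", "cp"] <- 2000
  expect_equal(estimate_heat_capacity(composition(0.75, 0.25), tab2), 3635)

  tab3 <- component_property_table()
  tab3["water", "rho"] <- 1000; tab3["protein", "rho"] <- 500
  eps <- volume_fractions(composition(0.5, 0.5), tab3)
  expect_equal(unname(eps[c("water", "protein")]), c(1 / 3, 2 / 3),
               tolerance = 1e-12)

  # equal densities: volume fractions reduce to mass fractions
  tab4 <- component_property_table(); tab4$rho <- rep(1050, 5)
  comp4 <- composition(0.4, 0.3, 0.2, 0.05, 0.05)
  expect_equal(unname(volume_fractions(comp4, tab4)), as.numeric(comp4))

  # conductivity limits: eps = 0.5/0.5 via equal densities, k = 0.6 / 0.2
  tab5 <- component_property_table()
  tab5$rho <- rep(1000, 5); tab5["water", "k"] <- 0.6
  tab5["protein", "k"] <- 0.2
  comp5 <- composition(0.5, 0.5)
  expect_equal(estimate_thermal_conductivity(comp5, tab5, g = 1), 0.3)
  expect_equal(estimate_thermal_conductivity(comp5, tab5, g = 0), 0.4)
  expect_equal(estimate_thermal_conductivity(comp5, tab5, g = 0.5), 0.35)
})

test_that("default composition reproduces the packaged typical product values", {
  comp <- default_composition()
  expect_equal(estimate_density(comp), 1064.5, tolerance = 0.005)
  expect_equal(estimate_heat_capacity(comp), 3535.5, tolerance = 0.005)
  expect_equal(estimate_thermal_conductivity(comp, g = 0.5), 0.47,
               tolerance = 0.005)
  p <- props_from_composition(comp)
  expect_s3_class(p, "thermo_props")
  expect_equal(p$alpha, p$k / (p$rho * p$cp))
})

test_that("perpendicular <= mixed <= parallel conductivity for random compositions", {
  set.seed(11)
  tab <- component_property_table()
  for (i in 1:25) {
    x <- as.numeric(stats::rgamma(5, 1)); x <- x / sum(x)
    comp <- composition(x[1], x[2], x[3], x[4], x[5])
    eps <- volume_fractions(comp, tab)
    k_par <- sum(eps * tab$k)
    k_per <- 1 / sum(eps / tab$k)
    g <- stats::runif(1)
    k_mix <- estimate_thermal_conductivity(comp, tab, g)
    expect_lte(k_per, k_mix + 1e-12)
    expect_lte(k_mix, k_par + 1e-12)
    expect_gte(k_per, min(tab$k) - 1e-12)
    expect_lte(k_par, max(tab$k) + 1e-12)
    # density and cp bounded by component extremes
    expect_true(estimate_density(comp, tab) >= min(tab$rho) &&
                  estimate_density(comp, tab) <= max(tab$rho))
    expect_true(estimate_heat_capacity(comp, tab) >= min(tab$cp) &&
                  estimate_heat_capacity(comp, tab) <= max(tab$cp))
  }
})

test_that("estimators are invariant to component reordering and scale correctly", {
  tab <- component_property_table()
  comp <- default_composition()
  perm <- c("ash", "fat", "water", "carbohydrate", "protein")
  tab_p <- tab[perm, ]
  expect_equal(estimate_density(comp, tab_p), estimate_density(comp, tab))
  expect_equal(estimate_heat_capacity(comp, tab_p),
               estimate_heat_capacity(comp, tab))
  expect_equal(estimate_thermal_conductivity(comp, tab_p, 0.4),
               estimate_thermal_conductivity(comp, tab, 0.4))
  # homogeneity: scaling all component densities by c scales rho_m by c
  for (c_fac in c(0.5, 2, 10)) {
    tab_s <- tab; tab_s$rho <- tab$rho * c_fac
    expect_equal(estimate_density(comp, tab_s),
                 c_fac * estimate_density(comp, tab), tolerance = 1e-12)
  }
})

test_that("invalid compositions and parameters are rejected", {
  expect_error(composition(0.6, 0.5), "sum")
  expect_error(composition(-0.1, 1.1), "\\[0, 1\\]")
  tab <- component_property_table()
  tab["fat", "rho"] <- -1
  expect_error(estimate_density(default_composition(), tab), "positive")
  expect_error(estimate_thermal_conductivity(default_composition(), g = 1.2),
               "g must")
  expect_error(estimate_thermal_conductivity(default_composition(), g = -.1),
               "g must")
  tabk <- component_property_table(); tabk["ash", "k"] <- 0
  expect_error(estimate_thermal_conductivity(default_composition(), tabk),
               "positive")
  expect_error(thermo_props(-1, 100, 0.5), "positive")
})
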