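test_that("inbreeding-rate arithmetic matches the breeding-program rules", {
  expect_equal(deltaF_from_Ne(50), 0.01)
  expect_equal(deltaF_from_Ne(100), 0.005)
  expect_equal(deltaF_from_Ne(1e12), 0, tolerance = 1e-10)
  expect_equal(ub_fA_from_deltaF(0.020, 0.01), 0.0298)
  expect_equal(ub_fA_from_deltaF(0.025, 0.01), 0.03475)
  expect_equal(ub_fA_from_deltaF(0, 0), 0)
})

test_that("truncation-selection sire counts solve the Ne equation", {
  expect_identical(ts_sire_count(50, 1000), 13L)
  expect_identical(ts_sire_count(50, 10000000), 13L)  # ceil(12.5) limit
  expect_identical(ts_sire_count(50, 50), 17L)
  expect_error(ts_sire_count(50, 10), "too small")
})

test_that("lambda interpolation reproduces its endpoints and arithmetic", {
  optima <- c(fB = 0.1, MC = 0.4, EBV = 1.2)
  refv <- c(fB = 0.2, MC = 0.7, EBV = 0.1)
  b0 <- derive_bounds(0, optima, refv)
  expect_equal(b0$ub_fB, 0.2)
  expect_equal(b0$lb_EBV, 0.1)
  b1 <- derive_bounds(1, optima, refv)
  expect_equal(b1$ub_fB, 0.1)
  expect_equal(b1$ub_MC, 0.4)
  expect_equal(derive_bounds(0.3, optima, refv)$ub_fB, 0.17)
  expect_error(derive_bounds(0.3, optima, refv, which = c("fB", "fD")),
               "missing")
})

test_that("selected-sire counting applies the non-zero threshold", {
  s <- count_selected(c(0.4999, 0.0001))
  expect_equal(s$fraction, 0.5)
  expect_equal(count_selected(rep(0.5 / 13, 13))$sd, 0)
  x <- numeric(200)
  x[1:13] <- 0.5 / 13
  expect_equal(count_selected(x)$fraction, 0.065)
})

test_that("scenario names parse into objective and constraint set", {
  p <- parse_scenario("maxEBV.A.D.MC")
  expect_equal(p$objective, "max_EBV")
  expect_equal(p$constraints, c("ub_fA", "ub_fD", "ub_MC"))
  expect_equal(parse_scenario("minfB.A")$objective, "min_fB")
  expect_error(parse_scenario("maxGain.A"), "unknown objective")
  expect_error(parse_scenario("minfB.Q"), "unknown constraint")
  sp <- scenario_spec("min_MC", list(ub_fA = 0.03, lb_EBV = 0.5))
  expect_equal(sp$name, "minMC.A.EBV")
})

test_that("reference and truncation baselines have the documented shape", {
  m <- fx$mixed_3gen
  cands <- toy_candidates(m, n_males = 2L, n_females = 3L,
                          ebv = c(2, 1, 0.5, -0.5, 0.3))
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  ref <- ref_scenario(cands, kin)
  expect_equal(unname(ref$c), rep(c(0.25, 0.5 / 3), c(2, 3)))
  expect_equal(ref$achieved[["fA"]],
               mean_kinship(ref$c, kin$fA))
  # REF EBV is nonzero when the sexes differ in mean EBV
  expect_false(isTRUE(all.equal(ref$achieved[["EBV"]], 0)))
  # TS: top sires by EBV at equal contributions, dominating REF's EBV
  ts <- suppressWarnings(ts_scenario(cands, kin, Ne_target = 3))
  expect_true(ts$achieved[["EBV"]] >= ref$achieved[["EBV"]])
  expect_equal(sum(ts$c_males > 0),
               min(ts_sire_count(3, length(cands$females)), 2L))
  # tie-break by ascending id when EBVs are equal
  cands2 <- cands
  cands2$data$ebv <- c(1, 1, 0, 0, 0)
  cands2 <- normalize_ebv(cands2)
  ts2 <- suppressWarnings(ts_scenario(cands2, kin, Ne_target = 3))
  picked <- names(ts2$c_males)[ts2$c_males > 0]
  expect_equal(picked, sort(cands$males)[seq_along(picked)])
})

test_that("unconstrained EBV maximization puts all male mass on the best sire", {
  m <- fx$mixed_3gen
  cands <- toy_candidates(m, n_males = 2L, n_females = 2L,
                          ebv = c(2, -1, 0.5, -0.5))
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  r <- solve_scenario(scenario_spec("max_EBV"), kin, cands)
  expect_equal(r$solver_status, "optimal")
  best <- cands$males[which.max(cands$data$ebv_norm[1:2])]
  expect_equal(unname(r$c_males[best]), 0.5, tolerance = 1e-5)
})

test_that("minimizing fA over unrelated non-inbred males is symmetric", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "E"), sire = NA, dam = NA,
    sex = c("M", "M", "M", "F", "F"), born = 1960, breed = "NAT"))
  org <- compute_mc(ped, classify_origin(ped, native_breeds = "NAT"))
  kin <- pedigree_kinships(ped, org)
  cands <- structure(list(
    males = c("A", "B", "C"), females = c("D", "E"),
    data = data.frame(id = c("A", "B", "C", "D", "E"),
                      sex = c("M", "M", "M", "F", "F"),
                      ebv = c(1, 2, 3, 0, 1),
                      mc = rep(0, 5))), class = "nocs_candidates")
  cands <- normalize_ebv(cands)
  r <- solve_scenario(scenario_spec("min_fA"), kin, cands)
  expect_equal(unname(r$c_males), rep(0.5 / 3, 3), tolerance = 1e-6)
})

test_that("convex scenarios match the simplex grid search on 3-male toys", {
  m <- fx$random_50
  cands <- toy_candidates(m, n_males = 3L, n_females = 3L, seed = 21L)
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  ref_fA <- mean_kinship(stats::setNames(
    rep(c(0.5 / 3, 0.5 / 3), c(3, 3)), cands$data$id), kin$fA)
  ubA <- ub_fA_from_deltaF(ref_fA, 0.02)
  cases <- list(
    list(obj = "min_fB", b = list(ub_fA = ubA)),
    list(obj = "min_fC", b = list(ub_fA = ubA)),
    list(obj = "min_MC", b = list(ub_fA = ubA)),
    list(obj = "max_EBV", b = list(ub_fA = ubA)),
    list(obj = "max_EBV", b = list(ub_fA = ubA,
                                   ub_MC = mean(cands$data$mc))))
  for (cs in cases) {
    g <- grid_search(kin, cands, cs$obj, cs$b, step = 1e-3)
    r <- solve_scenario(scenario_spec(cs$obj, cs$b), kin, cands)
    expect_equal(r$solver_status, "optimal", info = cs$obj)
    crit <- switch(cs$obj, min_fB = "fB", min_fC = "fC", min_MC = "MC",
                   max_EBV = "EBV")
    got <- r$achieved[[crit]]
    want <- if (cs$obj == "max_EBV") -g$value else g$value
    # the grid overestimates a minimum by at most its resolution
    expect_lt(abs(got - want), 5e-3)
    if (cs$obj != "max_EBV") expect_lt(got, want + 1e-9)
    else expect_gt(got, want - 1e-9)
  }
})

test_that("fD minimization matches the grid oracle and its fixed point", {
  m <- fx$random_50
  cands <- toy_candidates(m, n_males = 3L, n_females = 3L, seed = 21L)
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  ref_fA <- mean_kinship(stats::setNames(
    rep(c(0.5 / 3, 0.5 / 3), c(3, 3)), cands$data$id), kin$fA)
  ubA <- ub_fA_from_deltaF(ref_fA, 0.02)
  g <- grid_search(kin, cands, "min_fD", list(ub_fA = ubA), step = 1e-3)
  r <- minimize_fD(kin, cands, list(ub_fA = ubA))
  expect_equal(r$solver_status, "local")
  expect_lt(abs(r$achieved[["fD"]] - g$value), 5e-3)
  # Dinkelbach fixed point: numerator - fD * denominator vanishes
  num <- mean_kinship(r$c, kin$Knat)
  den <- mean_kinship(r$c, kin$fN)
  expect_lt(abs(num - r$achieved[["fD"]] * den), 1e-8)
  # the solution satisfies the kinship bound
  expect_lte(r$achieved[["fA"]], ubA + 1e-6)
})

test_that("degenerate bounds are reported infeasible, not clipped", {
  m <- fx$random_50
  cands <- toy_candidates(m, n_males = 3L, n_females = 3L, seed = 21L)
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  r <- solve_scenario(scenario_spec("max_EBV", list(ub_MC = 0)), kin,
                      cands)
  expect_equal(r$solver_status, "infeasible")
  expect_equal(r$violated, "ub_MC")
})

test_that("solved scenarios satisfy every stated constraint post hoc", {
  m <- fx$random_50
  cands <- toy_candidates(m, n_males = 3L, n_females = 3L, seed = 21L)
  kin <- pedigree_kinships(m$pedigree, m$origin, cands$data$id)
  b <- list(ub_fA = 0.2, ub_MC = mean(cands$data$mc) + 0.05,
            lb_EBV = -0.5)
  r <- solve_scenario(scenario_spec("max_EBV", b), kin, cands)
  expect_equal(r$solver_status, "optimal")
  expect_true(all(r$c >= -1e-9))
  expect_equal(sum(r$c_males), 0.5, tolerance = 1e-8)
  expect_equal(unname(sum(r$c)), 1, tolerance = 1e-8)
  expect_lte(r$achieved[["fA"]], b$ub_fA + 1e-6)
  expect_lte(r$achieved[["MC"]], b$ub_MC + 1e-6)
  expect_gte(r$achieved[["EBV"]], b$lb_EBV - 1e-6)
})
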