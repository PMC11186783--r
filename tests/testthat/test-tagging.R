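tags5 <- c("national", "european", "other_domain", "maritime", "boundary")

test_that("chemical regime follows the H2O2:HNO3 ratio rule", {
  expect_equal(regime(0.2, 1), "VOC-sensitive")
  expect_equal(regime(0.5, 1), "NOx-sensitive")
  expect_equal(regime(0.35, 1), "NOx-sensitive") # documented tie-break
  expect_equal(regime(1, 0), "NOx-sensitive")    # ratio -> infinity
  expect_error(regime(-0.1, 1), ">= 0")
  expect_error(regime(0.1, -1), ">= 0")
})

test_that("production is attributed proportionally to the limiting precursor", {
  st <- box_state(tags5, nox = c(national = 3, european = 1, other_domain = 0,
                                 maritime = 0, boundary = 0),
                  voc = c(national = 0, european = 0, other_domain = 5,
                          maritime = 0, boundary = 0))
  inc <- attribute_production(10, st, "NOx-sensitive")
  expect_equal(unname(inc), c(7.5, 2.5, 0, 0, 0))
  expect_equal(sum(inc), 10)
  # VOC regime uses VOC tracers instead
  inc <- attribute_production(10, st, "VOC-sensitive")
  expect_equal(unname(inc), c(0, 0, 10, 0, 0))
  # zero production, zero increments
  expect_equal(sum(attribute_production(0, st, "NOx-sensitive")), 0)
  # production with no limiting precursor is a model-consistency error
  empty <- box_state(tags5)
  expect_error(attribute_production(1, empty, "NOx-sensitive"),
               "model-consistency")
  # homogeneity of degree 1 in delta
  expect_equal(attribute_production(5, st, "NOx-sensitive") * 2,
               attribute_production(10, st, "NOx-sensitive"))
})

test_that("loss is attributed proportionally to current tagged ozone", {
  st <- box_state(c("a", "b"), o3 = c(a = 8, b = 2))
  expect_equal(unname(attribute_loss(5, st)), c(4, 1))
  expect_equal(unname(attribute_loss(10, st)), c(8, 2)) # loss = total -> zero
  expect_equal(sum(attribute_loss(0, st)), 0)
  expect_error(attribute_loss(11, st), "exceeds")
})

test_that("box step preserves tag additivity and honours trivial cases", {
  st <- box_state(tags5, o3 = c(national = 5, european = 3, other_domain = 1,
                                maritime = 0.5, boundary = 10))
  # zero rates leave the state unchanged
  st2 <- box_step(st, list())
  expect_equal(st2$o3, st$o3)
  # boundary-only inflow accrues entirely to the boundary tag
  empty <- box_state(tags5)
  for (k in 1:5) empty <- box_step(empty, list(inflow = 2))
  expect_equal(unname(empty$o3[c("national", "european", "other_domain",
                                 "maritime")]), rep(0, 4))
  expect_equal(unname(empty$o3["boundary"]), 10)
})

test_that("tag totals are conserved over random forcing sequences", {
  set.seed(99)
  st <- box_state(tags5)
  total <- 0
  for (i in 1:2000) {
    f <- list(
      nox_emis = setNames(runif(5, 0, 2), tags5),
      voc_emis = setNames(runif(5, 0, 2), tags5),
      production = runif(1, 0, 3),
      loss_rate = runif(1, 0, 0.1),
      dep_rate = runif(1, 0, 0.05),
      inflow = runif(1, 0, 1),
      h2o2 = runif(1, 0, 1), hno3 = runif(1, 0.1, 1)
    )
    # independent scalar bookkeeping of the same operations on the total
    avail <- sum(st[[if (regime(f$h2o2, f$hno3) == "NOx-sensitive") "nox"
                     else "voc"]]) +
      sum((if (regime(f$h2o2, f$hno3) == "NOx-sensitive") f$nox_emis
           else f$voc_emis))
    delta <- min(f$production, avail)
    total <- (sum(st$o3) + delta) * exp(-(f$loss_rate + f$dep_rate)) + f$inflow
    st <- box_step(st, f)
    expect_true(all(st$o3 >= 0) && all(st$nox >= 0) && all(st$voc >= 0))
    expect_equal(sum(st$o3), total, tolerance = 1e-9)
  }
})

test_that("equilibrium shares match a much longer explicit iteration", {
  f <- list(nox_emis = c(national = 2, european = 1, other_domain = 0.2,
                         maritime = 0.4, boundary = 0),
            voc_emis = 1, production = 3, loss_rate = 0.05, dep_rate = 0.02,
            inflow = 1.5, h2o2 = 1, hno3 = 1)
  s_short <- box_shares(box_equilibrium(tags5, f, n_steps = 1500))
  s_long <- box_shares(box_equilibrium(tags5, f, n_steps = 6000))
  expect_equal(s_short, s_long, tolerance = 1e-9)
  expect_equal(sum(s_long), 1, tolerance = 1e-12)
})

test_that("a scenario with no domestic precursors yields zero national share", {
  f <- list(nox_emis = c(national = 0, european = 3, other_domain = 0.5,
                         maritime = 0.5, boundary = 0),
            voc_emis = c(national = 0, european = 2, other_domain = 0.5,
                         maritime = 0.5, boundary = 0),
            production = 2, loss_rate = 0.05, dep_rate = 0.01, inflow = 1,
            h2o2 = 1, hno3 = 1)
  st <- box_equilibrium(tags5, f, n_steps = 1000)
  expect_equal(unname(box_shares(st)["national"]), 0)
  expect_gt(box_shares(st)["boundary"], 0)
})

test_that("the lattice advects boundary air west to east and conserves tags", {
  f <- list(nox_emis = c(national = 1, european = 0.5, other_domain = 0.1,
                         maritime = 0.2, boundary = 0),
            voc_emis = 0.5, production = 1, loss_rate = 0.05, dep_rate = 0.02,
            h2o2 = 1, hno3 = 1)
  run <- run_tagged_lattice(tags5, rep(list(f), 5), n_steps = 400,
                            wind_frac = 0.3, boundary_conc = 60,
                            record_every = 400)
  shares <- dplyr::mutate(
    dplyr::group_by(run, box),
    share = o3 / sum(o3))
  bshare <- shares$share[shares$tag == "boundary"]
  # the boundary (hemispheric) share decays moving downwind of the inlet
  expect_true(all(diff(bshare) < 0))
  expect_true(all(bshare > 0))
  # exposure-field conversion keeps values and layout
  tf <- tagged_field_from_lattice(run)
  expect_setequal(names(tf), c("day", "cell_id", "tag", "value_ugm3"))
  expect_equal(sort(unique(tf$cell_id)), 1:5)
})
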