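test_that("generated webs validate and balance on the first pass", {
  for (s in 1:100) {
    w <- generate_web(synthetic_web_spec(n_producers = 2, n_consumers = 5,
                                         n_detritus = 1, seed = s))
    expect_length(validate_model(w), 0)
    b <- solve_balance(w)
    expect_true(b$balanced)
    g <- b$model$groups
    liv <- g$role != "detritus"
    expect_true(all(g$EE[liv] > 0 & g$EE[liv] <= 0.95 + 1e-9))
    # drawn rates respect the P/Q band and consumers sit above TL 1
    cons <- g$role == "consumer"
    pq <- g$PB[cons] / g$QB[cons]
    expect_true(all(pq >= 0.1 - 1e-12 & pq <= 0.3 + 1e-12))
    expect_true(all(trophic_levels(w)[cons] > 1))
  }
})

test_that("generation is deterministic given the spec seed", {
  sp <- synthetic_web_spec(n_producers = 2, n_consumers = 6, seed = 123)
  expect_identical(generate_web(sp), generate_web(sp))
  sp2 <- synthetic_web_spec(n_producers = 2, n_consumers = 6, seed = 124)
  expect_false(identical(generate_web(sp), generate_web(sp2)))
})

test_that("consumer-free specs give trivially balanced acyclic systems", {
  w <- generate_web(synthetic_web_spec(n_producers = 2, n_consumers = 0,
                                       n_detritus = 1, seed = 5))
  b <- solve_balance(w)
  expect_true(b$balanced)
  expect_equal(finn_cycling(b$accounts, b$model)$FCI, 0)
})

test_that("spec validation rejects infeasible settings", {
  expect_error(synthetic_web_spec(n_producers = 0))
  expect_error(synthetic_web_spec(connectance = 0))
  expect_error(synthetic_web_spec(pq_range = c(0.3, 0.1)))
  expect_error(synthetic_web_spec(ee_range = c(0.1, 1.2)))
})

test_that("reef model fixture carries the published inputs intact", {
  fx <- core_fixture(diet = "none")
  g <- fx$groups
  expect_equal(nrow(g), 17)
  expect_equal(g$B[g$name == "Oyster"], 1333)
  expect_equal(g$B[g$name == "Detritus"], 130)
  expect_equal(unname(fx$reference$TL_range), c(1.00, 3.73))
  expect_equal(range(g$TL_ref), c(1.00, 3.73))
  # published P/Q column is recovered from P/B / Q/B to 3 decimals
  cons <- g$role == "consumer"
  pq_published <- c(0.188, 0.132, 0.206, 0.295, 0.140, 0.331, 0.351, 0.242,
                    0.328, 0.092, 0.159, 0.256, 0.230, 0.598)
  expect_equal(round(g$PB[cons] / g$QB[cons], 3), pq_published)
  # column checksums pin the fixture against silent edits
  expect_equal(sum(g$B), 2032.7938, tolerance = 1e-9)
  expect_equal(sum(g$PB, na.rm = TRUE), 367.01, tolerance = 1e-9)
  expect_equal(sum(g$QB, na.rm = TRUE), 258.97, tolerance = 1e-9)
})

test_that("survey fixtures match the published margins", {
  zoo <- plankton_fixture("zooplankton")
  expect_equal(sum(zoo$counts), 38)           # 6 + 12 + 20
  expect_equal(nrow(zoo$counts), 9)
  phy <- plankton_fixture("phytoplankton")
  expect_equal(nrow(phy$counts), 13)
  expect_equal(phy$counts["Paralia sulcata", "C"], 180)
  both <- plankton_fixture("all")
  expect_equal(nrow(both$counts), 22)

  ck <- reef_checklist_fixture()
  expect_equal(nrow(ck), 30)
  expect_equal(length(unique(ck$phylum)), 5)
})

test_that("diet reconstruction recovers exact small-web solutions", {
  g <- data.frame(
    name = c("p", "h", "c", "d"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(10, 1, 0.1, 10), PB = c(50, 5, 2, NA), QB = c(NA, 20, 8, NA),
    GS = c(0, 0.2, 0.2, 0))
  # chain targets (1, 2, 3, 1): predator must feed purely at TL 2
  rec <- reconstruct_diet_matrix(g, tl_target = c(1, 2, 3, 1),
                                 ee_target = rep(NA_real_, 4), seed = 2)
  expect_lt(rec$tl_residual, 0.02)
  expect_gt(rec$diet["c", "h"], 0.98)

  # target TL 2.5 over prey at TL 1 and TL 2 -> diet (0.5, 0.5)
  rec2 <- reconstruct_diet_matrix(g, tl_target = c(1, 2, 2.5, 1),
                                  ee_target = rep(NA_real_, 4), seed = 2)
  expect_equal(unname(rec2$diet["c", c("p", "h")] +
                        c(rec2$diet["c", "d"], 0)),
               c(0.5, 0.5), tolerance = 0.02)
})

test_that("the reconstructed reef diet matrix meets its calibration contract", {
  fx <- core_fixture(seed = 1)
  rec <- fx$reconstruction
  expect_lt(rec$tl_residual, 0.1)
  tl <- trophic_levels(fx$model)
  expect_equal(unname(tl), unname(rec$tl_achieved), tolerance = 1e-9)
  # balances with every living EE inside (0, 1]
  b <- solve_balance(fx$model)
  expect_true(b$balanced)
  # detritus EE lands near the published pool efficiency
  expect_equal(b$accounts$EE[b$accounts$role == "detritus"], 0.961,
               tolerance = 0.05)
})
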