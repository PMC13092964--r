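test_that("EE estimation matches hand mass-balance arithmetic", {
  # producer B=10, P/B=10; herbivore B=1, Q/B=10, diet 100% producer:
  # EE_producer = (1*10*1)/(10*10) = 0.1; herbivore has no predators -> EE 0
  b <- solve_balance(toy_chain_model())
  expect_equal(b$model$groups$EE[1], 0.1)
  expect_equal(b$model$groups$EE[2], 0)
  expect_true(b$balanced)
})

test_that("coupled unknown biomasses solve as one exact linear system", {
  # hand-derived: B_C1 = 1.5, B_P = (8*1.5 + 1.5)/8 = 1.6875
  g <- data.frame(
    name = c("P", "C1", "C2", "det"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B  = c(NA, NA, 0.5, 5),
    PB = c(10, 2, 1, NA),
    QB = c(NA, 8, 6, NA),
    EE = c(0.8, 0.5, NA, NA))
  diet <- matrix(0, 4, 4)
  diet[2, 1] <- 1
  diet[3, 1] <- 0.5; diet[3, 2] <- 0.5
  b <- solve_balance(food_web_model(g, diet))
  expect_equal(b$model$groups$B[2], 1.5, tolerance = 1e-12)
  expect_equal(b$model$groups$B[1], 1.6875, tolerance = 1e-12)
  # filled model satisfies the master equation
  ee <- oracle_ee(b$model)
  expect_equal(b$model$groups$EE[1:3], ee[1:3], tolerance = 1e-12)
})

test_that("solver EEs equal brute-force master-equation evaluation", {
  for (seed in c(2, 5, 17, 23)) {
    w <- random_small_web(seed, n_consumers = 3)   # <= 5 living groups
    b <- solve_balance(w)
    liv <- w$groups$role != "detritus"
    expect_equal(b$model$groups$EE[liv], oracle_ee(b$model)[liv],
                 tolerance = 1e-12)
  }
})

test_that("flow accounts follow the respiration/detritus partition", {
  fx <- core_fixture()
  b <- solve_balance(fx$model)
  acc <- b$accounts
  expect_equal(acc$Q[acc$group == "Oyster"], 1333 * 7.75)  # = 10330.75
  # consumers: Q = P + R + unassimilated
  cons <- acc$role == "consumer"
  expect_equal(acc$Q[cons],
               acc$P[cons] + acc$R[cons] + acc$Q[cons] * 0.2,
               tolerance = 1e-9)

  # producer with EE = 1 sends nothing to detritus
  m <- toy_chain_model()
  m$groups$EE[1] <- 1
  m$groups$B[1] <- NA
  acc1 <- solve_balance(m)$accounts
  expect_equal(acc1$FD[1], 0, tolerance = 1e-12)

  # P/Q = 0.9 with GS = 0.2 implies negative respiration
  bad <- toy_chain_model()
  bad$groups$PB[2] <- 9
  expect_error(solve_balance(bad), "negative respiration")
})

test_that("per-group residuals and detritus conservation hold on random webs", {
  for (seed in 1:25) {
    w <- random_small_web(seed, n_consumers = 5)
    b <- solve_balance(w)
    g <- b$model$groups
    liv <- g$role != "detritus"
    resid <- abs(g$B * g$PB * g$EE -
                   (b$accounts$M2 + g$Y + g$BA + g$E))[liv]
    expect_lt(max(resid / pmax(1, (g$B * g$PB)[liv])), 1e-6)
    # detritus pool: inflow - consumption - surplus export = 0, surplus >= 0
    det <- g$role == "detritus"
    inflow <- attr(b$accounts, "detritus_inflow")
    expect_gte(min(b$accounts$EX[det]), 0)
    expect_equal(unname(sum(inflow) - sum(b$accounts$M2[det]) -
                          sum(b$accounts$EX[det])), 0, tolerance = 1e-9)
  }
})

test_that("raising a predator biomass never lowers any prey EE", {
  for (seed in c(3, 9, 14)) {
    w <- random_small_web(seed, n_consumers = 4)
    base <- solve_balance(w)$model$groups$EE
    cons <- which(w$groups$role == "consumer")
    j <- cons[length(cons)]
    up <- w
    up$groups$B[j] <- up$groups$B[j] * 1.5
    bumped <- solve_balance(up)$model$groups$EE
    prey <- which(w$diet[j, seq_len(nrow(w$groups))] > 0 &
                    w$groups$role != "detritus")
    expect_true(all(bumped[prey] >= base[prey] - 1e-12))
  }
})

test_that("underdetermined structures are rejected with named causes", {
  m <- toy_chain_model()
  m$groups$B[2] <- NA          # herbivore now missing B and EE
  expect_error(solve_balance(m), "underdetermined")

  q <- toy_chain_model()
  q$groups$QB[2] <- NA
  q$groups$EE[2] <- 0.5        # known EE but no cannibalism to pin QB
  expect_error(solve_balance(q), "without cannibalism")
})

test_that("unknown QB is recovered through the cannibalism term", {
  # herbivore eats 80% producer, 20% itself; choose EE so QB = 10:
  # B*PB*EE = B*QB*0.2 + 0  ->  EE = QB*0.2/PB = 1 (PB=2, QB=10) -> use PB=4
  g <- data.frame(
    name = c("p", "h", "d"),
    role = c("producer", "consumer", "detritus"),
    B = c(10, 1, 5), PB = c(10, 4, NA), QB = c(NA, NA, NA),
    EE = c(NA, 0.5, NA))
  diet <- matrix(0, 3, 3)
  diet[2, 1] <- 0.8; diet[2, 2] <- 0.2
  b <- solve_balance(food_web_model(g, diet))
  # B*PB*EE = 1*4*0.5 = 2 = B*QB*0.2 -> QB = 10
  expect_equal(b$model$groups$QB[2], 10, tolerance = 1e-12)
})

test_that("fishing mortality perturbs Y = F*B and shifts EE by F/(P/B)", {
  fx <- core_fixture()
  m0 <- fx$model
  same <- apply_fishing_mortality(m0, "Oyster", 0)
  expect_equal(same$groups, m0$groups)   # F = 0 is the identity

  expect_error(apply_fishing_mortality(m0, "Kraken", 0.1), "unknown group")
  expect_error(apply_fishing_mortality(m0, "Oyster", -0.1), "non-negative")

  # with predation demand fixed, EE rises by exactly F / (P/B)
  w <- toy_chain_model()
  base <- solve_balance(w)$model$groups$EE[1]
  pert <- w
  pert$groups$B[1] <- 10     # keep B fixed
  pert <- apply_fishing_mortality(pert, "producer", 0.5)
  ee_f <- solve_balance(pert)$model$groups$EE[1]
  expect_equal(ee_f - base, 0.5 / 10, tolerance = 1e-12)
})

test_that("optional greedy rebalancer nudges EE>1 webs toward balance", {
  # overload the producer: tiny biomass against a large grazer demand
  g <- data.frame(
    name = c("p", "h", "d"),
    role = c("producer", "consumer", "detritus"),
    B = c(1, 1, 5), PB = c(10, 2, NA), QB = c(NA, 10.5, NA), EE = NA_real_)
  diet <- matrix(0, 3, 3); diet[2, 1] <- 1
  m <- food_web_model(g, diet)
  plain <- solve_balance(m)
  expect_false(plain$balanced)
  expect_equal(plain$ee_violations, "p")

  fixed <- solve_balance(m, rebalance = TRUE)
  expect_true(length(fixed$adjustments) > 0)
  expect_lt(max(fixed$model$groups$EE[1]), plain$model$groups$EE[1])
  expect_lte(fixed$model$groups$B[1], 1.1 + 1e-9)  # capped at +10%
})
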