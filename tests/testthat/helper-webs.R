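# Toy webs and independent oracles used across the suite. The oracles
# recompute quantities by direct arithmetic (loops, truncated series), never
# through the package's linear-algebra paths.

# producer -> herbivore -> carnivore chain with hand-set rates
toy_three_chain <- function() {
  g <- data.frame(
    name = c("prod", "herb", "carn", "det"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B  = c(10, 2, 0.5, 10),
    PB = c(10, 2, 1, NA),
    QB = c(NA, 10, 4, NA),
    EE = NA_real_
  )
  diet <- matrix(0, 4, 4)
  diet[2, 1] <- 1
  diet[3, 2] <- 1
  food_web_model(g, diet)
}

# producer + detritivore loop: consumer feeds half on detritus, closing a
# consumer -> detritus -> consumer cycle
toy_detritivore_web <- function(det_share = 0.5) {
  g <- data.frame(
    name = c("prod", "cons", "det"),
    role = c("producer", "consumer", "detritus"),
    B  = c(10, 2, 20),
    PB = c(15, 3, NA),
    QB = c(NA, 12, NA),
    EE = NA_real_
  )
  diet <- matrix(0, 3, 3)
  diet[2, 1] <- 1 - det_share
  diet[2, 3] <- det_share
  food_web_model(g, diet)
}

# web with diet imports and fishery catches diluting every trophic link, so
# the direct-impact matrix has spectral radius < 1 and the mixed-trophic-
# impact Neumann series converges (a plain two-link chain sits exactly at
# radius 1)
toy_dilute_web <- function(import1 = 0.5, import2 = 0.4, y_p = 6) {
  g <- data.frame(
    name = c("p", "c1", "c2", "det"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(10, 1, 0.5, 10), PB = c(10, 3, 2, NA), QB = c(NA, 10, 8, NA),
    EE = NA_real_, Y = c(y_p, 1, 0.2, 0))
  diet <- matrix(0, 4, 5)
  diet[2, 1] <- 1 - import1; diet[2, 5] <- import1
  diet[3, 1] <- 0.3; diet[3, 2] <- 0.2
  diet[3, 4] <- 1 - 0.5 - import2; diet[3, 5] <- import2
  food_web_model(g, diet)
}

# small random fully-specified web builder for oracle-equivalence checks:
# every parameter known except EE
random_small_web <- function(seed, n_consumers = 3) {
  generate_web(synthetic_web_spec(n_producers = 2, n_consumers = n_consumers,
                                  n_detritus = 1, seed = seed))
}

# --- oracles -----------------------------------------------------------

# master equation rearranged, evaluated by explicit loops
oracle_ee <- function(model) {
  g <- model$groups
  n <- nrow(g)
  ee <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (g$role[i] == "detritus") next
    m2 <- 0
    for (j in seq_len(n))
      if (g$role[j] == "consumer")
        m2 <- m2 + g$B[j] * g$QB[j] * model$diet[j, i]
    prod_i <- g$B[i] * g$PB[i]
    ee[i] <- if (prod_i > 0) (m2 + g$Y[i] + g$BA[i] + g$E[i]) / prod_i else 0
  }
  ee
}

# MTI by truncated Neumann series of the direct-impact matrix
oracle_mti <- function(direct, k_max = 50) {
  n <- nrow(direct)
  acc <- matrix(0, n, n)
  pw <- diag(n)
  for (k in seq_len(k_max)) {
    pw <- pw %*% direct
    acc <- acc + pw
  }
  acc
}

# Finn cycling by truncated geometric series of the input-structure matrix,
# assembled here by explicit loops over the accounts
oracle_fci <- function(model, accounts, k_max = 200) {
  g <- model$groups
  n <- nrow(g)
  fl <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (g$role[j] == "consumer")
      fl[i, j] <- fl[i, j] + accounts$Q[j] * model$diet[j, i]
  }
  det <- which(g$role == "detritus")
  liv <- which(g$role != "detritus")
  for (d in seq_along(det))
    fl[liv, det[d]] <- fl[liv, det[d]] +
      accounts$FD[liv] * model$detritus_fate[, d]
  t_in <- ifelse(g$role == "consumer", accounts$Q,
                 ifelse(g$role == "producer", accounts$P, 0))
  t_in[det] <- colSums(fl)[det]
  G <- matrix(0, n, n)
  for (j in seq_len(n)) if (t_in[j] > 0) G[, j] <- fl[, j] / t_in[j]
  N <- diag(n)
  pw <- diag(n)
  for (k in seq_len(k_max)) {
    pw <- pw %*% G
    N <- N + pw
  }
  njj <- diag(N)
  cycled <- sum(t_in[t_in > 0] * (njj[t_in > 0] - 1) / njj[t_in > 0])
  TST <- sum(accounts$Q) + sum(accounts$EX) + sum(accounts$R) +
    sum(accounts$FD[g$role != "detritus"])
  100 * cycled / TST
}
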