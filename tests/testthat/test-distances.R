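test_that("identical rows give zero distance under every model", {
  M <- matrix(rep(strsplit("ACDEFGHIKL", "")[[1]], 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  for (kind in c("p_distance", "poisson_gamma", "jtt_gamma")) {
    D <- pairwiseDistances(M, distanceModel(kind, alpha = 1))
    expect_equal(unname(distMatrix(D)), matrix(0, 3, 3), tolerance = 1e-10)
  }
})

test_that("gamma-corrected Poisson distance matches its closed forms", {
  expect_equal(poissonGammaDistance(0.5, 1), 1.0)
  expect_equal(poissonGammaDistance(0.19, 2), 2 * ((0.81)^(-1 / 2) - 1))
  expect_equal(poissonGammaDistance(0, 3), 0)
})

test_that("poisson_gamma is decreasing in alpha and bounded below by -log(1-p)", {
  for (p in c(0.05, 0.2, 0.5, 0.8)) {
    alphas <- c(0.3, 0.7, 1, 2, 5, 20)
    d <- poissonGammaDistance(p, alphas[1])
    for (a in alphas[-1]) {
      d2 <- poissonGammaDistance(p, a)
      expect_lt(d2, d)
      d <- d2
    }
    expect_gte(poissonGammaDistance(p, 1e6), -log(1 - p) - 1e-4)
    expect_gt(poissonGammaDistance(p, 2), -log(1 - p))
  }
})

test_that("the embedded JTT model matches an independent copy and is a proper generator", {
  Q <- jttRateMatrix()
  expect_equal(rowSums(Q), rep(0, 20), tolerance = 1e-12, ignore_attr = TRUE)
  pi <- connexo:::.JTT_FREQS / sum(connexo:::.JTT_FREQS)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  ## detailed balance (reversibility): pi_i q_ij = pi_j q_ji
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12, ignore_attr = TRUE)
  ## cross-check against phangorn's copy of the same published constants
  m <- get(".JTT", envir = environment(phangorn::dist.ml))
  S <- matrix(0, 20, 20); S[lower.tri(S)] <- m$Q; S <- S + t(S)
  pi2 <- m$bf / sum(m$bf)
  Q2 <- S * rep(pi2, each = 20); diag(Q2) <- -rowSums(Q2)
  Q2 <- Q2 / (-sum(pi2 * diag(Q2)))
  expect_equal(unname(Q), unname(Q2), tolerance = 1e-10)
})

test_that("JTT+Gamma inversion recovers the divergence of its own expected-p curve", {
  for (alpha in c(0.5, 1, 2)) {
    rates <- discreteGammaRates(alpha, 8)
    t0 <- c(0.05, 0.3, 1, 2.5)
    p <- connexo:::.jttExpectedP(t0, rates)
    expect_equal(jttGammaDistance(p, alpha, 8), t0, tolerance = 1e-6)
  }
  ## discrete gamma categories average to rate 1
  expect_equal(mean(discreteGammaRates(0.5, 8)), 1, tolerance = 1e-9)
  expect_equal(discreteGammaRates(1, 1), 1)
})

test_that("pairwise deletion uses only mutually ungapped columns", {
  rows <- c(a = "AAAAAAAAAA", b = "AAAAA-AAAC", c = "CAAAAAAAAA")
  M <- do.call(rbind, strsplit(rows, ""))
  rownames(M) <- names(rows)
  D <- pairwiseDistances(M, distanceModel("p_distance"))
  S <- comparableSites(D)
  expect_equal(S["a", "b"], 9L)
  expect_equal(S["a", "c"], 10L)
  expect_equal(distMatrix(D)["a", "b"], 1 / 9)
  expect_equal(distMatrix(D)["a", "c"], 1 / 10)
  ## removing the column gapped in b changes no distance involving b
  M2 <- M[, -6]
  D2 <- pairwiseDistances(M2, distanceModel("p_distance"))
  expect_equal(distMatrix(D2)["a", "b"], distMatrix(D)["a", "b"])
  expect_equal(distMatrix(D2)["b", "c"], distMatrix(D)["b", "c"])
  expect_equal(comparableSites(D2)["a", "b"], comparableSites(D)["a", "b"])
})

test_that("incomparable and saturated pairs are flagged, not truncated", {
  rows <- c(a = "AC----", b = "---DEF", c = "ACWDEF")
  M <- do.call(rbind, strsplit(rows, ""))
  rownames(M) <- names(rows)
  D <- pairwiseDistances(M, distanceModel("p_distance"))
  expect_equal(pairFlags(D)["a", "b"], "incomparable")
  expect_true(is.na(distMatrix(D)["a", "b"]))

  rows2 <- c(x = strrep("A", 30), y = strrep("R", 30), z = strrep("A", 30))
  M2 <- do.call(rbind, strsplit(rows2, ""))
  rownames(M2) <- names(rows2)
  D2 <- pairwiseDistances(M2, distanceModel("jtt_gamma", alpha = 1))
  expect_equal(pairFlags(D2)["x", "y"], "saturated")
  expect_true(is.na(distMatrix(D2)["x", "y"]))
  expect_equal(distMatrix(D2)["x", "z"], 0)
})

test_that("complete deletion drops every gapped column for all pairs", {
  rows <- c(a = "AAAAA", b = "A-AAC", c = "AAAAA")
  M <- do.call(rbind, strsplit(rows, ""))
  rownames(M) <- names(rows)
  D <- pairwiseDistances(M, distanceModel("p_distance", deletion = "complete"))
  expect_true(all(comparableSites(D)[upper.tri(matrix(0, 3, 3))] == 4L))
  expect_equal(distMatrix(D)["a", "b"], 1 / 4)
})

test_that("the JTT+Gamma estimator is close to truth on simulated pairs", {
  ## small simulation check (the full grid runs in the acceptance suite)
  set.seed(400)
  alpha <- 1; nsites <- 200; nrep <- 30; t0 <- 0.5
  pi <- connexo:::.JTT_FREQS / sum(connexo:::.JTT_FREQS)
  aa <- connexo:::.aaOrderJTT
  est <- numeric(nrep)
  for (r in seq_len(nrep)) {
    rates <- stats::rgamma(nsites, alpha, alpha)
    s1 <- sample(aa, nsites, replace = TRUE, prob = pi)
    s2 <- vapply(seq_len(nsites), function(i) {
      P <- jttTransitionMatrix(t0, rate = rates[i])
      sample(aa, 1, prob = P[s1[i], ])
    }, "")
    est[r] <- jttGammaDistance(mean(s1 != s2), alpha, 8)
  }
  expect_lt(abs(mean(est) - t0) / t0, 0.1)
})
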