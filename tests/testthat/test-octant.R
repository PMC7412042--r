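vcg_from <- function(m, rate = 100) vcg_record(m, rate)

test_that("octant assignment follows the sign-bit convention", {
  m <- rbind(c(1, 1, 1), c(-1, -1, -1), c(1, -1, 1), c(-1, 1, -1),
             c(1, 1, -1), c(0, 0, 0))
  s <- assign_octants(vcg_from(m))
  # brute-force sign oracle
  oracle <- apply(m, 1, function(v) 1 + 4 * (v[1] < 0) + 2 * (v[2] < 0) + (v[3] < 0))
  expect_equal(s$octant[1:5], oracle[1:5])
  expect_equal(s$octant[1], 1L)       # (+,+,+) -> octant 1
  expect_equal(s$octant[2], 8L)       # (-,-,-) -> octant 8
  expect_equal(s$octant[6], s$octant[5])  # zero vector keeps previous octant
  expect_equal(s$magnitude[1], sqrt(3))
})

test_that("local octant features match a brute-force statistics oracle", {
  # constant vector in octant 1
  cm <- matrix(rep(c(1, 2, 2), each = 10), 10)
  f <- local_octant_features(assign_octants(vcg_from(cm)))
  expect_equal(unname(f["Oct1Min"]), 3)
  expect_equal(unname(f["Oct1Avg"]), 3)
  expect_equal(unname(f["Oct1Max"]), 3)
  expect_equal(unname(f["Oct1Var"]), 0)
  expect_length(f, 48)
  # random trajectory vs direct per-octant statistics
  set.seed(41)
  m <- matrix(rnorm(300), 100, 3)
  s <- assign_octants(vcg_from(m))
  f2 <- local_octant_features(s)
  for (i in 1:8) {
    idx <- which(s$octant == i)
    if (!length(idx)) {
      expect_equal(unname(f2[paste0("Oct", i, "Min")]), 0)
      next
    }
    mg <- sqrt(rowSums(m[idx, , drop = FALSE]^2))
    expect_equal(unname(f2[paste0("Oct", i, "Min")]), min(mg))
    expect_equal(unname(f2[paste0("Oct", i, "Avg")]), mean(mg))
    expect_equal(unname(f2[paste0("Oct", i, "Var")]),
                 if (length(mg) > 1) var(mg) else 0)
    expect_equal(unname(f2[paste0("Oct", i, "Max")]), max(mg))
    k <- idx[which.max(mg)]
    expect_equal(unname(f2[paste0("Oct", i, "Azm")]),
                 atan2(m[k, 2], m[k, 1]) * 180 / pi)
    expect_equal(unname(f2[paste0("Oct", i, "Elv")]),
                 asin(m[k, 3] / max(mg)) * 180 / pi)
  }
})

test_that("residence features: sojourn conservation and transition rates", {
  # single-octant trajectory
  cm <- matrix(rep(c(1, 1, 1), each = 50), 50)
  f <- residence_features(assign_octants(vcg_from(cm, rate = 10)))
  expect_length(f, 12)
  expect_equal(unname(f["Oct1Num"]), 5)       # all 5 s in octant 1
  expect_equal(sum(f[1:8]), 5)
  expect_equal(unname(f[c("SlowTran", "FastTran", "MeanTran", "VarTran")]),
               rep(0, 4))
  # strictly alternating two-octant sequence: every boundary is a transition
  n <- 40
  m <- matrix(rep(c(1, 1, 1, -1, -1, -1), n / 2), ncol = 3, byrow = TRUE)
  s <- assign_octants(vcg_from(m, rate = 10))
  f2 <- residence_features(s, window = 1)
  # hand count: windows of 10 samples hold 9 boundaries, all transitions
  expect_equal(unname(f2["MeanTran"]), 9 / 1)
  expect_equal(unname(f2["SlowTran"]), 9)
  expect_equal(unname(f2["FastTran"]), 9)
  expect_equal(unname(f2["VarTran"]), 0)
  # sojourn conservation on a random walk
  set.seed(42)
  rw <- matrix(rnorm(900), 300, 3)
  fr <- residence_features(assign_octants(vcg_from(rw, rate = 30)))
  expect_equal(sum(fr[1:8]), 10)
})

test_that("transition features conserve total flow", {
  cm <- matrix(rep(c(1, 1, 1), each = 30), 30)
  f0 <- transition_features(assign_octants(vcg_from(cm)))
  expect_length(f0, 16)
  expect_true(all(f0 == 0))
  set.seed(43)
  m <- matrix(rnorm(600), 200, 3)
  s <- assign_octants(vcg_from(m, rate = 20))
  f <- transition_features(s)
  n_tr <- sum(s$octant[-1] != s$octant[-200])
  dur <- 200 / 20
  expect_equal(sum(f[1:8]), n_tr / dur)
  expect_equal(sum(f[9:16]), n_tr / dur)
  # per-octant flow conservation: |arrivals - departures| <= 1
  arr <- f[1:8] * dur; dep <- f[9:16] * dur
  expect_true(all(abs(arr - dep) <= 1))
})

test_that("octant network counts transitions, excludes self-loops", {
  # hand-written path 1 -> 2 -> 3 -> 1
  m <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, 1, 1))
  net <- build_octant_network(assign_octants(vcg_from(m)))
  expect_equal(net$weights[1, 2], 1L)
  expect_equal(net$weights[2, 3], 1L)
  expect_equal(net$weights[3, 1], 1L)
  expect_equal(net$total, 3L)
  expect_true(all(diag(net$weights) == 0))
  # single octant -> no edges
  net0 <- build_octant_network(assign_octants(vcg_from(matrix(1, 10, 3))))
  expect_equal(net0$total, 0L)
  # conservation: total = number of symbol changes
  set.seed(44)
  m2 <- matrix(rnorm(450), 150, 3)
  s <- assign_octants(vcg_from(m2))
  expect_equal(build_octant_network(s)$total,
               sum(s$octant[-1] != s$octant[-150]))
})

test_that("topology features: trivial cases and directed-ring oracle", {
  empty <- as_octant_network(matrix(0, 8, 8))
  f0 <- topology_features(empty)
  expect_length(f0, 85)
  expect_true(all(f0[paste0("Degr", 1:8)] == 0))
  expect_equal(unname(f0["Nden"]), 0)
  expect_equal(unname(f0["Jbl"]), 8)
  # 3-node directed ring, unit weights
  W <- matrix(0, 8, 8); W[1, 2] <- W[2, 3] <- W[3, 1] <- 1
  f <- topology_features(as_octant_network(W))
  expect_equal(unname(f[paste0("InDgr", 1:3)]), rep(1, 3))
  expect_equal(unname(f[paste0("OutDgr", 1:3)]), rep(1, 3))
  expect_equal(unname(f["DiameterNet"]), 2)  # longest shortest path in ring
  expect_equal(unname(f["RadiusNet"]), 2)
  expect_equal(unname(f[paste0("Ecc", 1:3)]), rep(2, 3))
  expect_equal(unname(f["Transi"]), 1)       # every 2-path closes
  expect_equal(unname(f["LambdaNet"]), 1.5)  # distances 1 and 2 per pair
  # full oracle agreement on the ring
  expect_equal(unname(f), unname(oracle_topology(W)), tolerance = 1e-10)
})

test_that("topology features match the brute-force oracle on random graphs", {
  set.seed(45)
  for (trial in 1:25) {
    n <- sample(2:4, 1)
    W <- matrix(sample(0:2, n * n, replace = TRUE, prob = c(0.5, 0.3, 0.2)), n)
    diag(W) <- 0
    got <- topology_features(as_octant_network(W))
    want <- oracle_topology(W)
    expect_equal(unname(got), unname(want), tolerance = 1e-9,
                 label = paste("trial", trial))
  }
})

test_that("path metrics agree with igraph where conventions coincide", {
  skip_if_not_installed("igraph")
  set.seed(47)
  for (trial in 1:10) {
    # strongly connected weighted graph: ring + random extra edges
    n <- 5
    W <- matrix(0, n, n)
    W[cbind(1:n, c(2:n, 1))] <- sample(1:3, n, replace = TRUE)
    extra <- which(W == 0 & diag(n) == 0)
    W[sample(extra, 4)] <- sample(1:3, 4, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                             weighted = TRUE)
    f <- topology_features(as_octant_network(W))
    D_ig <- igraph::distances(g, mode = "out",
                              weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(f["LambdaNet"]),
                 mean(D_ig[row(D_ig) != col(D_ig)]), tolerance = 1e-10)
    bt <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                              directed = TRUE)
    expect_equal(unname(f[paste0("NodeBet", 1:n)]), unname(bt),
                 tolerance = 1e-9)
    ecc <- apply(D_ig, 1, function(r) max(r[is.finite(r) & r > 0]))
    expect_equal(unname(f[paste0("Ecc", 1:n)]), unname(ecc), tolerance = 1e-10)
  }
})

test_that("full extractor: frozen layout, determinism, reversal symmetry", {
  set.seed(46)
  rec <- generate_dipole_record(dipole_params(duration = 10),
                                class_perturbation("LAD", angle = 40), seed = 6)
  f <- octant_features(rec$vcg)
  expect_length(f, 161)
  expect_identical(names(f), unlist(octant_feature_names(), use.names = FALSE))
  expect_equal(unname(table(attr(f, "groups"))[c("I", "II", "III", "IV")]),
               c(48L, 12L, 16L, 85L), ignore_attr = TRUE)
  expect_identical(f, octant_features(rec$vcg))
  # time reversal: sojourn invariant, in/out rates swapped
  revv <- vcg_record(unclass(rec$vcg)[nrow(rec$vcg):1, ], attr(rec$vcg, "rate"))
  fr <- octant_features(revv)
  expect_equal(f[paste0("Oct", 1:8, "Num")], fr[paste0("Oct", 1:8, "Num")])
  expect_equal(unname(f[paste0("InOct", 1:8, "Rate")]),
               unname(fr[paste0("OutOct", 1:8, "Rate")]))
})
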