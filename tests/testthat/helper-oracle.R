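# Independent brute-force oracle for the 85 octant-network topology features.
# Deliberately written with different algorithms than the implementation:
# shortest paths by exhaustive simple-path enumeration (not Floyd-Warshall),
# betweenness by explicit path counting (not Brandes), clustering by triple
# loops over the Fagiolo formula, modularity by iterating restricted-growth
# strings (not recursion over a pruned tree).  Feasible for n <= 4 nodes.

oracle_simple_paths <- function(W, s, t) {
  n <- nrow(W)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t && length(path) > 1) {
      paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (v in seq_len(n)) {
      if (W[u, v] > 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  paths
}

oracle_path_length <- function(W, path) {
  sum(1 / W[cbind(path[-length(path)], path[-1])])
}

# all-pairs shortest path lengths + the set of shortest paths per pair
oracle_shortest <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  SP <- vector("list", n * n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- oracle_simple_paths(W, s, t)
    if (!length(ps)) next
    lens <- vapply(ps, oracle_path_length, numeric(1), W = W)
    dmin <- min(lens)
    D[s, t] <- dmin
    SP[[(s - 1) * n + t]] <- ps[abs(lens - dmin) <= 1e-9]
  }
  list(D = D, SP = SP)
}

oracle_betweenness <- function(W, sp) {
  n <- nrow(W)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- sp$SP[[(s - 1) * n + t]]
    if (is.null(ps) || !length(ps)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(ps, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / length(ps)
    }
  }
  bc
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  wmax <- max(W)
  if (wmax == 0) return(numeric(n))
  Wh <- (W / wmax)^(1 / 3)
  A <- (W > 0) * 1
  cl <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      num <- num + (Wh[i, j] + Wh[j, i]) * (Wh[j, h] + Wh[h, j]) *
        (Wh[h, i] + Wh[i, h])
    }
    num <- num / 2
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    cl[i] <- if (den > 0) num / den else 0
  }
  cl
}

# next restricted-growth string (canonical set-partition encoding), or NULL
oracle_next_rgs <- function(a) {
  n <- length(a)
  for (i in rev(seq_len(n))[-n]) {
    prefix_max <- max(a[seq_len(i - 1)])
    if (a[i] <= prefix_max) {
      a[i] <- a[i] + 1L
      if (i < n) a[(i + 1):n] <- 1L
      return(a)
    }
  }
  NULL
}

oracle_modularity_max <- function(W) {
  B <- (W + t(W)) / 2
  two_m <- sum(B)
  if (two_m == 0) return(0)
  k <- rowSums(B)
  active <- which(k > 0)
  na <- length(active)
  qual <- function(memb) {
    q <- 0
    for (i in seq_len(na)) for (j in seq_len(na)) {
      if (memb[i] == memb[j])
        q <- q + B[active[i], active[j]] - k[active[i]] * k[active[j]] / two_m
    }
    q / two_m
  }
  a <- rep(1L, na)
  best <- qual(a)
  repeat {
    a <- oracle_next_rgs(a)
    if (is.null(a)) break
    best <- max(best, qual(a))
  }
  best
}

oracle_scc <- function(W) {
  n <- nrow(W)
  reach <- (W > 0)
  diag(reach) <- TRUE
  for (k in seq_len(n)) reach <- reach | (reach[, k] %o% reach[k, ])
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[reach[i, ] & reach[, i]] <- cur
    }
  }
  comp
}

# Full 85-feature oracle on an n x n weight matrix (n <= 8; padded to 8).
oracle_topology <- function(W) {
  n0 <- nrow(W)
  Wp <- matrix(0, 8, 8)
  Wp[seq_len(n0), seq_len(n0)] <- W
  W <- Wp
  nm <- pecgira::octant_feature_names()$IV
  out <- stats::setNames(rep(0, 85), nm)
  A <- (W > 0) * 1
  in_d <- colSums(A); out_d <- rowSums(A)
  out[paste0("InDgr", 1:8)] <- in_d
  out[paste0("OutDgr", 1:8)] <- out_d
  out[paste0("Degr", 1:8)] <- in_d + out_d
  out[paste0("InStr", 1:8)] <- colSums(W)
  out[paste0("OutStr", 1:8)] <- rowSums(W)
  out[paste0("Str", 1:8)] <- colSums(W) + rowSums(W)
  out[paste0("Clust", 1:8)] <- oracle_clustering(W)
  out["Jod"] <- sum(out_d > in_d)
  out["Jid"] <- sum(in_d > out_d)
  out["Jbl"] <- sum(in_d == out_d)
  e <- which(W > 0, arr.ind = TRUE)
  if (nrow(e) >= 2) {
    x <- out_d[e[, 1]]; y <- in_d[e[, 2]]
    if (stats::sd(x) > 0 && stats::sd(y) > 0) out["Rass"] <- stats::cor(x, y)
  }
  out["Kden"] <- sum(in_d + out_d > 0)
  out["Nden"] <- sum(A)
  out["K_den"] <- sum(A) / 56
  # directed transitivity: closed 3-cycles / directed 2-paths (i -> j -> k, i != k)
  tri <- 0; open <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (A[i, j] == 1 && A[j, k] == 1) {
      if (i != k) open <- open + 1
      if (A[k, i] == 1) tri <- tri + 1
    }
  }
  if (open > 0) out["Transi"] <- tri / open
  out["Qmod"] <- oracle_modularity_max(W)
  sp <- oracle_shortest(W)
  D <- sp$D
  off <- row(D) != col(D)
  fin <- off & is.finite(D)
  if (any(fin)) out["LambdaNet"] <- mean(D[fin])
  inv <- ifelse(is.finite(D) & off, 1 / D, 0)
  out["EfficiencyNet"] <- sum(inv[off]) / 56
  comp <- oracle_scc(W)
  comp[in_d + out_d == 0] <- 0L
  if (any(comp > 0)) {
    sizes <- table(comp[comp > 0])
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(comp == big)
    if (length(members) > 1) {
      ecc <- vapply(members, function(i) max(D[i, setdiff(members, i)]),
                    numeric(1))
      out[paste0("Ecc", members)] <- ecc
      out["RadiusNet"] <- min(ecc)
      out["DiameterNet"] <- max(ecc)
    }
  }
  out[paste0("NodeBet", 1:8)] <- oracle_betweenness(W, sp)
  out
}

# wrap a weight matrix as an octant_network without running a trajectory
as_octant_network <- function(W, duration = 10) {
  Wp <- matrix(0L, 8, 8)
  Wp[seq_len(nrow(W)), seq_len(ncol(W))] <- as.integer(W)
  structure(list(weights = Wp, total = sum(Wp), duration = duration),
            class = "octant_network")
}
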