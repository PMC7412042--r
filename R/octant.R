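# Octant random-walk representation of the VCG.
#
# The VCG trajectory is discretised into the 8 Cartesian octants; the
# resulting symbol sequence is summarised by four feature groups: local
# per-octant vector statistics (48), residence/sojourn features (12),
# transition rates (16) and topology metrics of the directed weighted
# octant-transition network (85) — 161 named features in total.

#' Names of the 161 octant features, by group
#'
#' @return Named list with character vectors `I`, `II`, `III`, `IV`
#'   (lengths 48, 12, 16, 85).
#' @export
octant_feature_names <- function() {
  oct8 <- function(stem, suffix = "") paste0(stem, 1:8, suffix)
  list(
    I = c(oct8("Oct", "Min"), oct8("Oct", "Avg"), oct8("Oct", "Var"),
          oct8("Oct", "Max"), oct8("Oct", "Elv"), oct8("Oct", "Azm")),
    II = c(oct8("Oct", "Num"), "SlowTran", "FastTran", "MeanTran", "VarTran"),
    III = c(oct8("InOct", "Rate"), oct8("OutOct", "Rate")),
    IV = c(oct8("InDgr"), oct8("OutDgr"), oct8("Degr"),
           oct8("InStr"), oct8("OutStr"), oct8("Str"), oct8("Clust"),
           "Jod", "Jid", "Jbl", "Rass", "Kden", "Nden", "K_den",
           "Transi", "Qmod", "LambdaNet", "EfficiencyNet",
           oct8("Ecc"), "RadiusNet", "DiameterNet", oct8("NodeBet")))
}

#' Assign each VCG sample to a Cartesian octant
#'
#' Octant index `1 + 4*[X<0] + 2*[Y<0] + [Z<0]`: the X sign is the high bit,
#' so octants 1-4 share the positive-X half-space and 5-8 the negative-X
#' half-space.  Zero-magnitude samples keep the previous sample's octant.
#'
#' @param vcg a [vcg_record()].
#' @param convention permutation applied to the default octant numbering
#'   (length-8 integer vector), for alternative axis-to-side mappings.
#' @return Object of class `octant_sequence`: `octant` (integer in 1..8 per
#'   sample), `magnitude` (mV), `azimuth`/`elevation` (degrees), `rate`.
#' @export
assign_octants <- function(vcg, convention = 1:8) {
  stopifnot(inherits(vcg, "vcg_record"))
  m <- unclass(vcg)
  X <- m[, 1]; Y <- m[, 2]; Z <- m[, 3]
  mag <- sqrt(X^2 + Y^2 + Z^2)
  oct <- 1L + 4L * (X < 0) + 2L * (Y < 0) + 1L * (Z < 0)
  zero <- which(mag == 0)
  for (i in zero) if (i > 1) oct[i] <- oct[i - 1]
  oct <- convention[oct]
  az <- atan2(Y, X) * 180 / pi
  el <- ifelse(mag > 0, asin(pmin(1, pmax(-1, Z / pmax(mag, .Machine$double.eps)))) * 180 / pi, 0)
  structure(list(octant = as.integer(oct), magnitude = mag,
                 azimuth = az, elevation = el, rate = attr(vcg, "rate")),
            class = "octant_sequence")
}

#' Local octant features (group I, 48 values)
#'
#' Per octant: minimal, average, variance and maximal vector magnitude, plus
#' elevation and azimuth of the maximal vector.  Octants never visited take
#' the fill value so the vector is always finite.
#'
#' @param seq an [assign_octants()] result.
#' @param fill value for statistics of unvisited octants (default 0).
#' @return Named numeric vector of length 48.
#' @export
local_octant_features <- function(seq, fill = 0) {
  out <- stats::setNames(rep(fill, 48), octant_feature_names()$I)
  for (i in 1:8) {
    idx <- which(seq$octant == i)
    if (length(idx) == 0) next
    m <- seq$magnitude[idx]
    out[paste0("Oct", i, "Min")] <- min(m)
    out[paste0("Oct", i, "Avg")] <- mean(m)
    out[paste0("Oct", i, "Var")] <- if (length(m) > 1) stats::var(m) else 0
    k <- idx[which.max(m)]
    out[paste0("Oct", i, "Max")] <- max(m)
    out[paste0("Oct", i, "Elv")] <- seq$elevation[k]
    out[paste0("Oct", i, "Azm")] <- seq$azimuth[k]
  }
  out
}

# Per-boundary transition indicator (length n-1).
transition_indicator <- function(oct) {
  n <- length(oct)
  if (n < 2) return(logical(0))
  oct[-1] != oct[-n]
}

#' Octant residence features (group II, 12 values)
#'
#' Sojourn time per octant (seconds) plus minimum / maximum / mean / variance
#' of the octant-transition rate over sliding windows.
#'
#' @param seq an [assign_octants()] result.
#' @param window sliding-window length in seconds (default 1).
#' @return Named numeric vector of length 12.
#' @export
residence_features <- function(seq, window = 1) {
  nm <- octant_feature_names()$II
  out <- stats::setNames(numeric(12), nm)
  oct <- seq$octant; n <- length(oct); rate <- seq$rate
  cnt <- tabulate(oct, nbins = 8)
  out[1:8] <- cnt / rate
  tr <- transition_indicator(oct)
  W <- min(max(2L, round(window * rate)), n)
  # windowed transition counts over all start positions, via cumulative sums
  cs <- c(0, cumsum(as.numeric(tr)))
  starts <- seq_len(n - W + 1L)
  counts <- cs[starts + W - 1L] - cs[starts]
  rates <- counts / (W / rate)
  out["SlowTran"] <- min(rates)
  out["FastTran"] <- max(rates)
  out["MeanTran"] <- mean(rates)
  out["VarTran"] <- if (length(rates) > 1) stats::var(rates) else 0
  out
}

#' Octant transition-rate features (group III, 16 values)
#'
#' Arrival rate to and departure rate from each octant, per second of
#' observation.
#'
#' @param seq an [assign_octants()] result.
#' @return Named numeric vector of length 16.
#' @export
transition_features <- function(seq) {
  nm <- octant_feature_names()$III
  out <- stats::setNames(numeric(16), nm)
  oct <- seq$octant; n <- length(oct)
  dur <- n / seq$rate
  tr <- which(transition_indicator(oct))
  arr <- tabulate(oct[tr + 1L], nbins = 8)
  dep <- tabulate(oct[tr], nbins = 8)
  out[1:8] <- arr / dur
  out[9:16] <- dep / dur
  out
}

#' Build the directed weighted octant-transition network
#'
#' Nodes are the 8 octants; the weight of edge i -> j (i != j) is the number
#' of consecutive-sample transitions from octant i to octant j.
#'
#' @param seq an [assign_octants()] result.
#' @return Object of class `octant_network`: `weights` (8 x 8 integer matrix,
#'   zero diagonal), `total` transitions, `duration` (s).
#' @export
build_octant_network <- function(seq) {
  oct <- seq$octant; n <- length(oct)
  W <- matrix(0L, 8, 8)
  if (n >= 2) {
    from <- oct[-n]; to <- oct[-1]
    keep <- from != to
    if (any(keep)) {
      tb <- table(factor(from[keep], levels = 1:8),
                  factor(to[keep], levels = 1:8))
      W <- matrix(as.integer(tb), 8, 8)
    }
  }
  structure(list(weights = W, total = sum(W), duration = n / seq$rate),
            class = "octant_network")
}

#' @export
print.octant_network <- function(x, ...) {
  cat(sprintf("<octant_network> 8 nodes, %d edges, %d transitions over %.1f s\n",
              sum(x$weights > 0), x$total, x$duration))
  invisible(x)
}

# All-pairs shortest paths (Floyd-Warshall) with edge length = 1/weight.
octant_distances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# Exact maximum modularity of the symmetrised network over all set partitions
# of the active nodes (feasible because n <= 8: Bell(8) = 4140 partitions).
max_modularity <- function(W) {
  B <- (W + t(W)) / 2
  two_m <- sum(B)
  if (two_m == 0) return(0)
  k <- rowSums(B)
  active <- which(k > 0)
  na <- length(active)
  Bm <- B[active, active, drop = FALSE] - outer(k[active], k[active]) / two_m
  best <- -Inf
  part <- integer(na)
  recurse <- function(i, maxc) {
    if (i > na) {
      S <- outer(part, part, `==`)
      q <- sum(Bm * S) / two_m
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (c in seq_len(maxc + 1L)) {
      part[i] <<- c
      recurse(i + 1L, max(maxc, c))
    }
  }
  recurse(1L, 0L)
  best
}

# Node betweenness centrality (Brandes) with edge length = 1/weight; directed,
# endpoints excluded, unnormalised.
node_betweenness <- function(W) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    pred <- vector("list", n)
    visited <- rep(FALSE, n)
    order_stack <- integer(0)
    repeat {
      cand <- which(!visited & is.finite(dist))
      if (length(cand) == 0) break
      u <- cand[which.min(dist[cand])]
      visited[u] <- TRUE
      order_stack <- c(order_stack, u)
      for (v in which(is.finite(len[u, ]))) {
        alt <- dist[u] + len[u, v]
        if (alt < dist[v] - 1e-12) {
          dist[v] <- alt; sigma[v] <- sigma[u]; pred[[v]] <- u
        } else if (abs(alt - dist[v]) <= 1e-12) {
          sigma[v] <- sigma[v] + sigma[u]; pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_stack)) {
      for (u in pred[[v]])
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  bc
}

# Strongly connected components from the finite-distance relation.
scc_membership <- function(D) {
  mutual <- is.finite(D) & is.finite(t(D))
  diag(mutual) <- TRUE
  comp <- integer(nrow(D))
  cur <- 0L
  for (i in seq_len(nrow(D))) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[mutual[i, ]] <- cur
    }
  }
  comp
}

#' Topology features of the octant network (group IV, 85 values)
#'
#' Degrees, strengths, Fagiolo directed-weighted clustering, degree-balance
#' counts, assortativity (Pearson correlation of source out-degree vs target
#' in-degree over edges), density, directed transitivity, exactly maximised
#' modularity of the symmetrised network, and shortest-path metrics with edge
#' length `1/weight` under the reachable-pair convention (unreachable pairs
#' excluded from averages; eccentricity, radius and diameter computed on the
#' largest strongly connected component).  A disconnected or empty network
#' never raises an error.
#'
#' @param net a [build_octant_network()] result.
#' @param fill value for undefined entries (default 0).
#' @return Named numeric vector of length 85.
#' @export
topology_features <- function(net, fill = 0) {
  nm <- octant_feature_names()$IV
  out <- stats::setNames(rep(fill, 85), nm)
  W <- net$weights
  A <- (W > 0) * 1L
  in_d <- colSums(A); out_d <- rowSums(A)
  in_s <- colSums(W); out_s <- rowSums(W)
  out[paste0("InDgr", 1:8)] <- in_d
  out[paste0("OutDgr", 1:8)] <- out_d
  out[paste0("Degr", 1:8)] <- in_d + out_d
  out[paste0("InStr", 1:8)] <- in_s
  out[paste0("OutStr", 1:8)] <- out_s
  out[paste0("Str", 1:8)] <- in_s + out_s

  # Fagiolo directed weighted clustering
  wmax <- max(W)
  if (wmax > 0) {
    Wh <- (W / wmax)^(1 / 3)
    S <- Wh + t(Wh)
    num <- diag(S %*% S %*% S) / 2
    dtot <- in_d + out_d
    dbi <- diag(A %*% A)
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    cl <- ifelse(den > 0, num / den, fill)
    out[paste0("Clust", 1:8)] <- cl
  }

  out["Jod"] <- sum(out_d > in_d)
  out["Jid"] <- sum(in_d > out_d)
  out["Jbl"] <- sum(in_d == out_d)

  edges <- which(W > 0, arr.ind = TRUE)
  if (nrow(edges) >= 2) {
    x <- out_d[edges[, 1]]; y <- in_d[edges[, 2]]
    if (stats::sd(x) > 0 && stats::sd(y) > 0)
      out["Rass"] <- stats::cor(x, y)
  }

  out["Kden"] <- sum(in_d + out_d > 0)
  out["Nden"] <- sum(A)
  out["K_den"] <- sum(A) / (8 * 7)

  A2 <- A %*% A
  paths2 <- sum(A2) - sum(diag(A2))
  if (paths2 > 0) out["Transi"] <- sum(diag(A2 %*% A)) / paths2

  out["Qmod"] <- max_modularity(W)

  D <- octant_distances(W)
  off <- row(D) != col(D)
  finite_off <- off & is.finite(D)
  if (any(finite_off)) out["LambdaNet"] <- mean(D[finite_off])
  inv <- ifelse(is.finite(D) & off, 1 / D, 0)
  out["EfficiencyNet"] <- sum(inv[off]) / (8 * 7)

  comp <- scc_membership(D)
  comp[in_d + out_d == 0] <- 0L      # isolated nodes are not a component
  if (any(comp > 0)) {
    sizes <- table(comp[comp > 0])
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(comp == big)
    if (length(members) > 1) {
      ecc <- vapply(members, function(i) {
        max(D[i, setdiff(members, i)])
      }, numeric(1))
      out[paste0("Ecc", members)] <- ecc
      out["RadiusNet"] <- min(ecc)
      out["DiameterNet"] <- max(ecc)
    }
  }

  out[paste0("NodeBet", 1:8)] <- node_betweenness(W)
  out
}

#' Extract the full 161-feature octant vector from a VCG record
#'
#' Concatenation of the four groups in the frozen order of
#' [octant_feature_names()]: 48 local octant statistics, 12 residence
#' features, 16 transition rates, 85 network-topology metrics.
#'
#' @param vcg a [vcg_record()].
#' @param window residence-feature window, s.
#' @return Named numeric vector of length 161 with attribute `groups`.
#' @export
octant_features <- function(vcg, window = 1) {
  seq <- assign_octants(vcg)
  net <- build_octant_network(seq)
  nm <- octant_feature_names()
  out <- c(local_octant_features(seq), residence_features(seq, window),
           transition_features(seq), topology_features(net))
  stopifnot(identical(names(out), unlist(nm, use.names = FALSE)))
  attr(out, "groups") <- rep(names(nm), times = lengths(nm))
  out
}

#' Feature matrix for a cohort
#'
#' @param cohort an `ecg_cohort` or a list of [vcg_record()] objects.
#' @param use for an `ecg_cohort`: `"vcg"` extracts from the ground-truth
#'   dipole trajectories; `"ecg"` runs [ecg_to_vcg()] on the 12-lead records
#'   first, i.e. the same transform path a digitized/reconstructed record
#'   takes through the pipeline — use it when the features feed a model that
#'   will score pipeline output.
#' @param matrix lead-to-VCG transform for `use = "ecg"`.
#' @return List: `x` (matrix, rows = records, 161 named columns), `labels`
#'   (character, NULL for plain VCG lists).
#' @export
cohort_features <- function(cohort, use = c("vcg", "ecg"),
                            matrix = INVERSE_DOWER) {
  use <- match.arg(use)
  vcgs <- if (inherits(cohort, "ecg_cohort")) {
    if (use == "ecg")
      lapply(cohort$records, function(r) ecg_to_vcg(r$ecg, matrix))
    else lapply(cohort$records, `[[`, "vcg")
  } else cohort
  x <- t(vapply(vcgs, function(v) octant_features(v), numeric(161)))
  labels <- if (inherits(cohort, "ecg_cohort")) cohort$labels else NULL
  list(x = x, labels = labels)
}
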