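# Nonparametric point-wise tests, sensor-time cluster-based permutation
# inference, effect sizes, and cross-method correlation.
#
# The permutation scheme exchanges conditions within subjects (sign flips of
# the paired differences). Because |differences| are invariant under a sign
# flip, the ranks of the signed-rank statistic are computed once and reused
# across permutations, which keeps 1000+ permutations cheap.

# Internal: per-column signed-rank machinery on a subjects x points matrix
# of paired differences. Zero differences are dropped; ties are mid-ranked;
# the normal approximation uses the tie-corrected variance.
srm_prepare <- function(d) {
  S <- nrow(d); P <- ncol(d)
  absd <- abs(d)
  zero <- !is.finite(d) | absd == 0
  R <- matrix(0, S, P)
  mu <- sigma <- numeric(P)
  for (p in seq_len(P)) {
    keep <- !zero[, p]
    n <- sum(keep)
    if (n == 0L) next
    r <- rank(absd[keep, p])          # mid-ranks for ties
    R[keep, p] <- r
    mu[p] <- n * (n + 1) / 4
    tie_tab <- table(r)
    ties <- sum(tie_tab^3 - tie_tab)
    sigma[p] <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - ties / 48)
  }
  list(R = R, pos = d > 0 & !zero, neg = d < 0 & !zero, mu = mu,
       sigma = sigma)
}

# z for a given per-subject sign-flip vector (+1 keeps, -1 swaps
# conditions). Uses the continuity-corrected normal approximation, as in
# wilcox.test.
srm_z <- function(prep, flips) {
  pos <- prep$pos
  if (any(flips < 0)) {
    f <- flips < 0
    pos[f, ] <- prep$neg[f, , drop = FALSE]
  }
  wplus <- colSums(prep$R * pos)
  delta <- wplus - prep$mu
  z <- sign(delta) * pmax(abs(delta) - 0.5, 0) / prep$sigma
  z[!is.finite(z)] <- 0
  z
}

#' Point-wise Wilcoxon signed-rank map
#'
#' Paired signed-rank test of `a` versus `b` at every channel and time
#' point, using the tie-corrected normal approximation. Zero differences are
#' dropped; points where all differences are zero get z = 0, p = 1.
#'
#' @param a,b subject x channel x time arrays (paired; `b` may be a scalar,
#'   e.g. 0 for a one-sample test against zero).
#' @param min_subjects minimum number of subjects required.
#' @return list of class `stat_map` with `z` and `p_point`
#'   (channels x times matrices).
#' @export
signed_rank_map <- function(a, b = 0, min_subjects = 5L) {
  a <- as_sct(a)
  if (length(b) == 1L) b <- array(b, dim = dim(a))
  b <- as_sct(b)
  if (!all(dim(a) == dim(b))) {
    stop_classed("invalid_argument", "paired arrays must share a shape")
  }
  if (dim(a)[1] < min_subjects) {
    stop_classed("invalid_argument", "need at least %d subjects",
                 min_subjects)
  }
  d <- a - b
  dm <- matrix(d, nrow = dim(d)[1])
  prep <- srm_prepare(dm)
  z <- srm_z(prep, rep(1, nrow(dm)))
  p <- 2 * stats::pnorm(-abs(z))
  p[prep$mu == 0] <- 1
  nc <- dim(a)[2]; nt <- dim(a)[3]
  structure(list(z = matrix(z, nc, nt), p_point = matrix(p, nc, nt)),
            class = "stat_map")
}

# Coerce subject x time matrices to subject x 1 x time arrays.
as_sct <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), 1L, ncol(x)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Channel adjacency from a 2-D sensor layout
#'
#' Channels are adjacent when their layout distance is below
#' `factor` x the median nearest-neighbor distance. The resulting relation
#' is symmetric and irreflexive. A single channel yields an empty graph
#' (time-only clustering).
#'
#' @param positions channels x 2 coordinate matrix.
#' @param factor distance threshold multiplier.
#' @return list (one entry per channel) of adjacent channel indices, class
#'   `neighbor_graph`.
#' @export
channel_neighbors <- function(positions, factor = 1.3) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 1L) {
    return(structure(list(integer(0)), class = "neighbor_graph"))
  }
  dm <- as.matrix(stats::dist(positions))
  diag(dm) <- Inf
  thresh <- factor * stats::median(apply(dm, 1, min))
  adj <- lapply(seq_len(n), function(i) which(dm[i, ] <= thresh))
  structure(adj, class = "neighbor_graph")
}

# Connected components of a channels x times logical mask, under adjacency
# in time (consecutive samples, same channel) and space (neighboring
# channels, same time point). Returns a list of 2-column index matrices.
find_clusters <- function(mask, neighbors = NULL) {
  nc <- nrow(mask); nt <- ncol(mask)
  if (nc == 1L) {                      # time-only clustering via run lengths
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- cbind(1L, starts[i]:ends[i])
    }
    return(out)
  }
  if (is.null(neighbors)) {
    stop_classed("invalid_argument",
                 "multichannel clustering requires a neighbor graph")
  }
  lab <- matrix(0L, nc, nt)
  nxt <- 0L
  out <- list()
  for (c0 in seq_len(nc)) for (t0 in seq_len(nt)) {
    if (!mask[c0, t0] || lab[c0, t0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(c0, t0), ncol = 2)
    lab[c0, t0] <- nxt
    members <- queue
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      cc <- cur[1]; tt <- cur[2]
      cand <- rbind(
        if (tt > 1L) c(cc, tt - 1L),
        if (tt < nt) c(cc, tt + 1L),
        if (length(neighbors[[cc]])) cbind(neighbors[[cc]], tt)
      )
      if (!is.null(cand)) {
        for (r in seq_len(nrow(cand))) {
          ci <- cand[r, 1]; ti <- cand[r, 2]
          if (mask[ci, ti] && lab[ci, ti] == 0L) {
            lab[ci, ti] <- nxt
            queue <- rbind(queue, c(ci, ti))
            members <- rbind(members, c(ci, ti))
          }
        }
      }
    }
    out[[nxt]] <- members
  }
  out
}

#' Cluster-based permutation test on paired sensor-time data
#'
#' Point-wise signed-rank tests of `a` vs `b`; suprathreshold points
#' (two-tailed point p below `cluster_alpha`) are grouped by adjacency in
#' time and across neighboring channels, separately by sign, and each
#' cluster's mass (sum of z) is compared with a permutation null built from
#' the maximum absolute cluster mass under random within-subject condition
#' swaps. The observed statistic is included in the permutation count, so
#' the smallest achievable two-tailed p is exactly `2 / n_permutations`.
#'
#' @param a,b subject x channel x time arrays (`b` may be the scalar 0 for a
#'   one-sample test).
#' @param neighbors a [channel_neighbors()] graph (`NULL` for single-channel
#'   data: time-only clustering).
#' @param n_permutations number of permutations (>= 100), observed included.
#' @param cluster_alpha two-tailed point-wise threshold forming clusters.
#' @param seed permutation seed.
#' @return object of class `cluster_result`: list with `clusters` (each
#'   holding `members` (channel, time index pairs), `sign`, `mass`, `p`
#'   two-tailed), the point-wise `z` and `p_point` maps, per-point Cohen's d
#'   (`effect_d`), `null_max`, `n_permutations`, `cluster_alpha`.
#' @export
cluster_permutation <- function(a, b = 0, neighbors = NULL,
                                n_permutations = 1000, cluster_alpha = 0.05,
                                seed = NULL) {
  if (n_permutations < 100) {
    stop_classed("invalid_argument", "need at least 100 permutations")
  }
  a <- as_sct(a)
  if (length(b) == 1L) b <- array(b, dim = dim(a))
  b <- as_sct(b)
  stopifnot(all(dim(a) == dim(b)))
  S <- dim(a)[1]; nc <- dim(a)[2]; nt <- dim(a)[3]
  d <- a - b
  dm <- matrix(d, nrow = S)
  prep <- srm_prepare(dm)
  zthr <- stats::qnorm(1 - cluster_alpha / 2)

  cluster_stats <- function(z) {
    zm <- matrix(z, nc, nt)
    res <- list()
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) zm > zthr else zm < -zthr
      for (cl in find_clusters(mask, neighbors)) {
        res[[length(res) + 1L]] <- list(
          members = cl, sign = if (sgn > 0) "+" else "-",
          mass = sum(zm[cl]))
      }
    }
    res
  }

  z_obs <- srm_z(prep, rep(1, S))
  obs <- cluster_stats(z_obs)
  obs_max <- if (length(obs)) max(abs(vapply(obs, `[[`, 0, "mass"))) else 0

  null_max <- numeric(n_permutations)
  null_max[1] <- obs_max
  with_seed(seed, {
    for (r in seq_len(n_permutations - 1L)) {
      flips <- sample(c(-1, 1), S, replace = TRUE)
      zp <- srm_z(prep, flips)
      cls <- cluster_stats(zp)
      null_max[r + 1L] <-
        if (length(cls)) max(abs(vapply(cls, `[[`, 0, "mass"))) else 0
    }
  })

  clusters <- lapply(obs, function(cl) {
    p_one <- mean(null_max >= abs(cl$mass))
    cl$p <- min(1, 2 * p_one)
    cl
  })

  # dependent-samples Cohen's d at every point
  dmean <- colMeans(dm)
  dsd <- apply(dm, 2, stats::sd)
  effect_d <- matrix(ifelse(dsd > 0, dmean / dsd, NA_real_), nc, nt)

  p <- 2 * stats::pnorm(-abs(z_obs))
  p[prep$mu == 0] <- 1
  structure(list(clusters = clusters,
                 z = matrix(z_obs, nc, nt),
                 p_point = matrix(p, nc, nt),
                 effect_d = effect_d, null_max = null_max,
                 n_permutations = n_permutations,
                 cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), %d permutations (p floor %.4g)\n",
              length(x$clusters), x$n_permutations, 2 / x$n_permutations))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %d points, mass %.2f, p = %.4g\n",
                cl$sign, nrow(cl$members), cl$mass, cl$p))
  }
  invisible(x)
}

#' Smallest cluster p-value, optionally restricted by sign
#'
#' @param result a [cluster_permutation()] result.
#' @param sign `"+"`, `"-"`, or `NULL` for either.
#' @return the smallest two-tailed cluster p (1 when no cluster matches).
#' @export
min_cluster_p <- function(result, sign = NULL) {
  cl <- result$clusters
  if (!is.null(sign)) cl <- Filter(function(c) c$sign == sign, cl)
  if (!length(cl)) return(1)
  min(vapply(cl, `[[`, 0, "p"))
}

#' Mask of sensor-time points inside significant clusters
#'
#' @param result a [cluster_permutation()] result.
#' @param alpha cluster-level significance threshold.
#' @param sign `"+"`, `"-"`, or `NULL` for either.
#' @return channels x times logical matrix.
#' @export
cluster_mask <- function(result, alpha = 0.05, sign = NULL) {
  m <- matrix(FALSE, nrow(result$z), ncol(result$z))
  for (cl in result$clusters) {
    if (!is.null(sign) && cl$sign != sign) next
    if (cl$p <= alpha) m[cl$members] <- TRUE
  }
  m
}

#' Cohen's d for dependent samples
#'
#' Mean of the paired differences divided by their sample standard
#' deviation.
#'
#' @param differences per-subject paired differences (>= 2).
#' @return scalar d.
#' @export
cohens_d_dependent <- function(differences) {
  if (length(differences) < 2L) {
    stop_classed("invalid_argument", "need at least 2 differences")
  }
  s <- stats::sd(differences)
  if (s == 0) {
    stop_classed("undefined_effect",
                 "all differences equal: effect size undefined")
  }
  mean(differences) / s
}

#' Spearman correlation of two summary indices with spatial cluster inference
#'
#' Per channel, the Spearman rank correlation across subjects between two
#' per-subject summary indices (e.g. pseudotrial vs TTV effect magnitudes).
#' Channels whose approximate point p falls below `point_alpha` are grouped
#' into spatial clusters (by sign), and each cluster's mass (sum of
#' Fisher-z statistics) is compared with a null built by randomly shuffling
#' subjects of the second index.
#'
#' @param index_a,index_b subject x channel matrices (pairwise-complete;
#'   >= 5 complete pairs required per channel, otherwise that channel's rho
#'   is `NA`).
#' @param neighbors a [channel_neighbors()] graph (`NULL` for a single
#'   channel).
#' @param n_permutations permutations, observed included.
#' @param point_alpha point-wise threshold forming clusters.
#' @param seed permutation seed.
#' @return list with `rho` (per channel), `p_point`, `clusters` (members,
#'   sign, mass, p), `n_permutations`.
#' @export
spearman_cluster_corr <- function(index_a, index_b, neighbors = NULL,
                                  n_permutations = 1000, point_alpha = 0.05,
                                  seed = NULL) {
  index_a <- as.matrix(index_a); index_b <- as.matrix(index_b)
  stopifnot(all(dim(index_a) == dim(index_b)))
  S <- nrow(index_a); nc <- ncol(index_a)

  chan_stats <- function(ib) {
    rho <- p <- zz <- rep(NA_real_, nc)
    for (c in seq_len(nc)) {
      ok <- stats::complete.cases(index_a[, c], ib[, c])
      n <- sum(ok)
      if (n < 5L) next
      if (stats::sd(index_a[ok, c]) == 0 || stats::sd(ib[ok, c]) == 0) next
      r <- stats::cor(index_a[ok, c], ib[ok, c], method = "spearman")
      rho[c] <- r
      zz[c] <- atanh(min(max(r, -0.999999), 0.999999)) * sqrt(n - 3)
      p[c] <- 2 * stats::pnorm(-abs(zz[c]))
    }
    list(rho = rho, p = p, z = zz)
  }

  comp_clusters <- function(st) {
    res <- list()
    sig <- which(!is.na(st$p) & st$p < point_alpha)
    for (sgn in c(1, -1)) {
      cand <- sig[sign(st$z[sig]) == sgn]
      if (!length(cand)) next
      # spatial components among the significant channels
      seen <- logical(nc)
      for (c0 in cand) {
        if (seen[c0]) next
        comp <- c0; seen[c0] <- TRUE; queue <- c0
        while (length(queue)) {
          cur <- queue[1]; queue <- queue[-1]
          nb <- if (is.null(neighbors)) integer(0) else neighbors[[cur]]
          new <- intersect(nb, cand)
          new <- new[!seen[new]]
          seen[new] <- TRUE
          comp <- c(comp, new); queue <- c(queue, new)
        }
        res[[length(res) + 1L]] <- list(
          members = comp, sign = if (sgn > 0) "+" else "-",
          mass = sum(st$z[comp]))
      }
    }
    res
  }

  obs <- chan_stats(index_b)
  obs_cl <- comp_clusters(obs)
  obs_max <- if (length(obs_cl)) {
    max(abs(vapply(obs_cl, `[[`, 0, "mass")))
  } else 0
  null_max <- numeric(n_permutations)
  null_max[1] <- obs_max
  with_seed(seed, {
    for (r in seq_len(n_permutations - 1L)) {
      st <- chan_stats(index_b[sample.int(S), , drop = FALSE])
      cls <- comp_clusters(st)
      null_max[r + 1L] <-
        if (length(cls)) max(abs(vapply(cls, `[[`, 0, "mass"))) else 0
    }
  })
  clusters <- lapply(obs_cl, function(cl) {
    cl$p <- min(1, 2 * mean(null_max >= abs(cl$mass)))
    cl
  })
  list(rho = obs$rho, p_point = obs$p, clusters = clusters,
       n_permutations = n_permutations)
}
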