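#' Ring adjacency over channels
#'
#' Simple symmetric neighbour structure (each channel adjacent to its two
#' ring neighbours) used as the default for synthetic grids; supply a real
#' cap neighbour list for recorded layouts.
#'
#' @param n_channels channel count.
#' @return list of integer neighbour vectors, one per channel.
#' @export
ring_adjacency <- function(n_channels) {
  if (n_channels == 1) return(list(integer(0)))
  lapply(seq_len(n_channels), function(i) {
    nb <- c(i - 1L, i + 1L)
    nb[nb == 0L] <- n_channels
    nb[nb == n_channels + 1L] <- 1L
    sort(unique(nb[nb != i]))
  })
}

# Precompute the neighbour list of every bin of a channels x freqs x times
# grid: 4-connectivity in the time-frequency plane plus the channel
# adjacency at the same (f, t).
.grid_neighbors <- function(nch, nf, nt, adjacency) {
  stopifnot(length(adjacency) == nch)
  for (i in seq_len(nch)) {
    if (i %in% adjacency[[i]]) stop("adjacency must have no self-edges")
    for (j in adjacency[[i]])
      if (!(i %in% adjacency[[j]])) stop("adjacency must be symmetric")
  }
  idx <- function(c, f, t) (t - 1L) * nf * nch + (f - 1L) * nch + c
  nb <- vector("list", nch * nf * nt)
  for (t in seq_len(nt)) for (f in seq_len(nf)) for (c in seq_len(nch)) {
    cur <- integer(0)
    if (f > 1L) cur <- c(cur, idx(c, f - 1L, t))
    if (f < nf) cur <- c(cur, idx(c, f + 1L, t))
    if (t > 1L) cur <- c(cur, idx(c, f, t - 1L))
    if (t < nt) cur <- c(cur, idx(c, f, t + 1L))
    if (length(adjacency[[c]])) cur <- c(cur, idx(adjacency[[c]], f, t))
    nb[[idx(c, f, t)]] <- cur
  }
  nb
}

# compress a neighbour list into 0-based CSR form for the compiled
# component labeller
.compress_neighbors <- function(neighbors) {
  lens <- lengths(neighbors)
  list(adj = as.integer(unlist(neighbors, use.names = FALSE) - 1L),
       offsets = as.integer(c(0L, cumsum(lens))))
}

# connected components among `active` bins (logical over the flattened
# grid); returns an integer label vector (0 = inactive)
.components <- function(active, nb) {
  .label_components_cpp(active, nb$adj, nb$offsets)
}

# per-bin paired t-statistics against zero for a subjects x bins matrix,
# exploiting that sign flips leave sum(x^2) unchanged
.tstats <- function(X, flips = NULL) {
  n <- nrow(X)
  ss <- colSums(X^2)
  m <- if (is.null(flips)) colMeans(X) else as.vector(flips %*% X) / n
  v <- (ss - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# signed supra-threshold cluster masses for a t-map; positive and negative
# clusters are formed separately
.cluster_masses <- function(tmap, thresh, nb, want_members = TRUE) {
  masses <- numeric(0)
  members <- list()
  for (sgn in c(1, -1)) {
    active <- sgn * tmap > thresh
    if (!any(active)) next
    labels <- .components(active, nb)
    nk <- max(labels)
    m <- unname(rowsum(tmap[labels > 0L], labels[labels > 0L])[, 1])
    masses <- c(masses, m)
    if (want_members)
      for (k in seq_len(nk))
        members[[length(members) + 1L]] <- which(labels == k)
  }
  list(masses = masses, members = members)
}

#' Cluster-based permutation test over an electrode-frequency-time grid
#'
#' Paired t-tests against zero at every bin of a subjects x channels x
#' freqs x times array (condition differences or modulations), thresholding
#' at the bin-level alpha, joining supra-threshold bins of equal sign under
#' channel adjacency plus 4-connectivity in the time-frequency plane, and
#' comparing each cluster's summed t (mass) against the permutation null of
#' the maximum absolute cluster mass over subject-level sign flips.
#' Corrected p-values are \code{(1 + #null >= observed) / (1 + n_perm)}.
#' When \code{n_perm} meets or exceeds the number of distinct sign flips,
#' the null is enumerated exactly and noted in the result.
#'
#' @param data subjects x channels x freqs x times array.
#' @param adjacency channel neighbour list (default ring adjacency).
#' @param n_perm number of permutations (default 1000).
#' @param bin_alpha bin-level two-sided threshold (default 0.05).
#' @param seed integer seed for the random sign flips.
#' @return a \code{cluster_result}: list of clusters (bins, sign, mass,
#'   p), the bin t-map, threshold, n_perm and whether enumeration was
#'   exact.
#' @export
cluster_permutation <- function(data, adjacency = NULL, n_perm = 1000L,
                                bin_alpha = 0.05, seed = 1L) {
  stopifnot(length(dim(data)) == 4)
  n_sub <- dim(data)[1]
  if (n_sub < 2) stop("need at least 2 subjects")
  nch <- dim(data)[2]; nf <- dim(data)[3]; nt <- dim(data)[4]
  adjacency <- adjacency %||% ring_adjacency(nch)
  nb <- .compress_neighbors(.grid_neighbors(nch, nf, nt, adjacency))
  X <- matrix(data, nrow = n_sub)  # bins flattened in (ch, f, t) order
  thresh <- stats::qt(1 - bin_alpha / 2, df = n_sub - 1)
  tobs <- .tstats(X)
  obs <- .cluster_masses(tobs, thresh, nb)
  exact <- 2^n_sub <= n_perm
  flips <- if (exact) {
    g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
    n_perm <- nrow(g)
    g
  } else {
    with_seed(seed,
              matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                     nrow = n_perm))
  }
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    tm <- .tstats(X, flips = flips[p, , drop = FALSE])
    cm <- .cluster_masses(tm, thresh, nb, want_members = FALSE)
    null_max[p] <- if (length(cm$masses)) max(abs(cm$masses)) else 0
  }
  clusters <- lapply(seq_along(obs$masses), function(k) {
    mass <- obs$masses[k]
    list(bins = obs$members[[k]], sign = sign(mass), mass = mass,
         p = (1 + sum(null_max >= abs(mass))) / (1 + n_perm))
  })
  clusters <- clusters[order(vapply(clusters,
                                    function(cl) -abs(cl$mass), 0))]
  structure(list(clusters = clusters, tmap = array(tobs, dim(data)[-1]),
                 threshold = thresh, n_perm = n_perm, exact = exact,
                 dims = dim(data)[-1]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), %d permutations%s\n",
              length(x$clusters), x$n_perm,
              if (x$exact) " (exact enumeration)" else ""))
  for (cl in head(x$clusters, 5))
    cat(sprintf("  sign %+d  mass %.1f  size %d  p = %.4g\n",
                cl$sign, cl$mass, length(cl$bins), cl$p))
  invisible(x)
}

#' Paired two-sided permutation test
#'
#' Sign-flip permutation null of the mean paired difference; exact
#' enumeration of all 2^n flips when feasible within \code{n_perm},
#' Monte-Carlo otherwise. When the observed statistic exceeds every
#' permutation the p-value is reported at the resolution floor
#' \code{1 / n_perm} (attainable only under exact enumeration, where the
#' identity flip always ties).
#'
#' @param x,y paired vectors per subject.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with \code{p}, observed mean difference \code{statistic},
#'   \code{n_perm}, \code{exact}.
#' @export
perm_test_paired <- function(x, y, n_perm = 10000L, seed = 1L) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  obs <- mean(d)
  exact <- 2^n <= n_perm
  if (exact) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(flips %*% d) / n
    p <- mean(abs(null) >= abs(obs) - 1e-12)
  } else {
    null <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm)
      as.vector(flips %*% d) / n
    })
    p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
  }
  list(p = p, statistic = obs, n_perm = if (exact) length(null) else n_perm,
       exact = exact)
}
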