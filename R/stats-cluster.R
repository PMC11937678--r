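# Mass-univariate testing of time-frequency maps: pixelwise t statistics,
# suprathreshold clustering (sign-aware connected components), cluster-mass
# permutation null, and Benjamini-Hochberg FDR across clusters.

# Connected-component labeling of a logical matrix (4- or 8-connectivity).
label_clusters <- function(mask, connectivity = 4) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    cur <- cur + 1L
    stack <- matrix(c(i, j), ncol = 2)
    labels[i, j] <- cur
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- cur
          stack <- rbind(stack, c(r, c))
        }
      }
    }
  }
  labels
}

# Stack maps (list of matrices or n x f x t array) into an n x P matrix.
stack_maps <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) {
    n <- dim(maps)[1]
    return(list(X = matrix(maps, nrow = n), dim = dim(maps)[2:3]))
  }
  if (!is.list(maps) || length(maps) == 0) stop("maps must be a non-empty list of matrices", call. = FALSE)
  d <- dim(maps[[1]])
  X <- t(vapply(maps, function(m) {
    if (!identical(dim(m), d)) stop("maps must share the frequency x time grid", call. = FALSE)
    as.numeric(m)
  }, numeric(prod(d))))
  list(X = X, dim = d)
}

# Vectorized pixelwise t maps. One-sample: optional sign vector; two-sample:
# pooled-variance t from a group indicator.
pixel_t_onesample <- function(X, signs = rep(1, nrow(X))) {
  n <- nrow(X)
  Xs <- X * signs
  m <- colMeans(Xs)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.eps) / n)
}

pixel_t_twosample <- function(X, is_a) {
  n1 <- sum(is_a); n2 <- sum(!is_a)
  m1 <- colMeans(X[is_a, , drop = FALSE])
  m2 <- colMeans(X[!is_a, , drop = FALSE])
  ss1 <- colSums(X[is_a, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[!is_a, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp2, .Machine$double.eps) * (1 / n1 + 1 / n2))
}

# Largest cluster mass (sum |t| over a sign-consistent suprathreshold
# component) of a t map; 0 when no pixel is suprathreshold.
max_cluster_mass <- function(tmat, tcrit, connectivity) {
  mass <- 0
  for (sgn in c(1, -1)) {
    mask <- sgn * tmat >= tcrit
    if (!any(mask)) next
    lab <- label_clusters(mask, connectivity)
    mass <- max(mass, max(tapply(abs(tmat[mask]), lab[lab > 0], sum)))
  }
  mass
}

#' Cluster-mass permutation test with FDR correction on time-frequency maps
#'
#' Pixelwise t map (one-sample against zero with a sign-flip null, or
#' two-sample with a group-label permutation null), thresholded at the
#' pixel-level `threshold_p`; sign-consistent connected components form
#' clusters scored by their mass (sum of |t|). Each cluster's p value is the
#' permutation probability that the maximum null cluster mass reaches its
#' mass; Benjamini-Hochberg FDR is applied across clusters.
#'
#' @param maps_a List of frequency x time matrices (or an n x f x t array):
#'   first group, or the only group for the one-sample test.
#' @param maps_b Second group (`NULL` for one-sample against zero).
#' @param threshold_p Pixel-level two-sided threshold p.
#' @param connectivity 4 or 8.
#' @param n_perm Number of permutations.
#' @param fdr_q FDR level for the significance mask.
#' @param seed Optional seed for the permutation draw.
#' @return List of class `cluster_test`: `t_map`, `threshold_t`, `clusters`
#'   (data frame: `id`, `sign`, `n_pixels`, `mass`, `p`, `q`),
#'   `significant_mask`, `n_perm`.
#' @export
cluster_fdr_map <- function(maps_a, maps_b = NULL, threshold_p = 0.05,
                            connectivity = 4, n_perm = 1000, fdr_q = 0.05,
                            seed = NULL) {
  A <- stack_maps(maps_a)
  if (is.null(maps_b)) {
    if (nrow(A$X) < 2) stop("one-sample cluster test needs >= 2 maps", call. = FALSE)
    X <- A$X
    df <- nrow(X) - 1
    t_obs <- pixel_t_onesample(X)
    perm_fun <- function() pixel_t_onesample(X, sample(c(-1, 1), nrow(X), TRUE))
  } else {
    B <- stack_maps(maps_b)
    if (!identical(A$dim, B$dim)) stop("groups must share the map grid", call. = FALSE)
    if (nrow(A$X) < 2 || nrow(B$X) < 2) stop("need >= 2 maps per group", call. = FALSE)
    X <- rbind(A$X, B$X)
    is_a <- c(rep(TRUE, nrow(A$X)), rep(FALSE, nrow(B$X)))
    df <- nrow(X) - 2
    t_obs <- pixel_t_twosample(X, is_a)
    perm_fun <- function() pixel_t_twosample(X, sample(is_a))
  }
  tcrit <- stats::qt(1 - threshold_p / 2, df)
  dimm <- A$dim
  t_map <- matrix(t_obs, dimm[1], dimm[2])

  clusters <- data.frame(id = integer(0), sign = integer(0),
                         n_pixels = integer(0), mass = numeric(0))
  sig_mask <- matrix(FALSE, dimm[1], dimm[2])
  cluster_px <- list()
  next_id <- 0L
  for (sgn in c(1L, -1L)) {
    mask <- sgn * t_map >= tcrit
    if (!any(mask)) next
    lab <- label_clusters(mask, connectivity)
    for (l in seq_len(max(lab))) {
      px <- which(lab == l)
      next_id <- next_id + 1L
      clusters <- rbind(clusters, data.frame(
        id = next_id, sign = sgn, n_pixels = length(px),
        mass = sum(abs(t_map[px]))))
      cluster_px[[next_id]] <- px
    }
  }

  if (nrow(clusters) > 0) {
    null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      tm <- matrix(perm_fun(), dimm[1], dimm[2])
      max_cluster_mass(tm, tcrit, connectivity)
    }, numeric(1)))
    clusters$p <- vapply(clusters$mass, function(m) {
      (1 + sum(null_max >= m)) / (1 + n_perm)
    }, numeric(1))
    clusters$q <- stats::p.adjust(clusters$p, method = "BH")
    for (i in which(clusters$q <= fdr_q)) sig_mask[cluster_px[[i]]] <- TRUE
  } else {
    clusters$p <- numeric(0); clusters$q <- numeric(0)
  }

  structure(list(t_map = t_map, threshold_t = tcrit, clusters = clusters,
                 significant_mask = sig_mask, n_perm = n_perm),
            class = "cluster_test")
}
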