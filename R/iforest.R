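## Isolation forest (Liu, Ting & Zhou 2008), the anomaly scorer behind
## guided_outlier_removal. Trees isolate points by recursive random
## axis-aligned splits; anomalous points have short average path lengths.
## score(x) = 2^(-E[h(x)] / c(psi)) in (0, 1), higher = more anomalous.

## average unsuccessful-search path length in a BST of n points
c_factor <- function(n) {
  ifelse(n > 2, 2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n,
         ifelse(n == 2, 1, 0))
}

## one tree over subsample rows; flat arrays for fast vectorized traversal
grow_itree <- function(x, depth_limit) {
  max_nodes <- 2L * nrow(x) + 2L
  feat <- integer(max_nodes); split <- numeric(max_nodes)
  left <- integer(max_nodes); right <- integer(max_nodes)
  size <- integer(max_nodes); depth <- integer(max_nodes)
  n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > length(feat)) { # grow arrays (rare)
      feat <<- c(feat, integer(max_nodes)); split <<- c(split, numeric(max_nodes))
      left <<- c(left, integer(max_nodes)); right <<- c(right, integer(max_nodes))
      size <<- c(size, integer(max_nodes)); depth <<- c(depth, integer(max_nodes))
    }
    n_nodes
  }
  build <- function(rows, d) {
    id <- new_node()
    depth[id] <<- d
    size[id] <<- length(rows)
    if (length(rows) <= 1 || d >= depth_limit) {
      feat[id] <<- 0L
      return(id)
    }
    ## draw a random split feature; retry a few times if it is constant on
    ## this node (cheaper than scanning all columns for usable ones)
    f <- 0L
    for (try in 1:8) {
      fc <- sample.int(ncol(x), 1)
      v <- x[rows, fc]
      lo <- min(v); hi <- max(v)
      if (hi > lo) { f <- fc; break }
    }
    if (f == 0L) {
      feat[id] <<- 0L
      return(id)
    }
    s <- runif(1, lo, hi)
    go_left <- v < s
    feat[id] <<- f
    split[id] <<- s
    left[id] <<- build(rows[go_left], d + 1L)
    right[id] <<- build(rows[!go_left], d + 1L)
    id
  }
  build(seq_len(nrow(x)), 0L)
  list(feat = feat[1:n_nodes], split = split[1:n_nodes],
       left = left[1:n_nodes], right = right[1:n_nodes],
       size = size[1:n_nodes], depth = depth[1:n_nodes])
}

## vectorized path length of all rows of x through one tree
itree_path <- function(tree, x) {
  node <- rep(1L, nrow(x))
  active <- tree$feat[node] > 0L
  while (any(active)) {
    idx <- which(active)
    nd <- node[idx]
    f <- tree$feat[nd]
    goes_left <- x[cbind(idx, f)] < tree$split[nd]
    node[idx] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
    active[idx] <- tree$feat[node[idx]] > 0L
  }
  tree$depth[node] + c_factor(tree$size[node])
}

#' Isolation-forest anomaly scores
#'
#' @param x numeric matrix (samples x features).
#' @param n_trees number of isolation trees.
#' @param subsample subsample size per tree (capped at `nrow(x)`).
#' @param seed integer seed.
#' @return Numeric anomaly scores in (0, 1), one per row; higher is more
#'   anomalous.
#' @export
iforest_score <- function(x, n_trees = 200, subsample = 256, seed = 1L) {
  x <- as.matrix(x)
  psi <- min(subsample, nrow(x))
  with_seed(seed, {
    depth_limit <- ceiling(log2(max(psi, 2)))
    paths <- matrix(NA_real_, nrow(x), n_trees)
    for (t in seq_len(n_trees)) {
      rows <- sample.int(nrow(x), psi)
      tree <- grow_itree(x[rows, , drop = FALSE], depth_limit)
      paths[, t] <- itree_path(tree, x)
    }
    2^(-rowMeans(paths) / c_factor(psi))
  })
}
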