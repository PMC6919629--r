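# Pairwise global-alignment distances and rooted UPGMA clustering of
# precursor sets, with Newick serialization and group cutting.
#
# All tie-breaks are fixed for determinism: alignment traceback prefers
# diagonal, then up (gap in the second sequence), then left; UPGMA merges
# the tied pair whose (lexicographically smallest member, partner) label
# pair sorts first.

#' Global alignment fractional identity
#'
#' Needleman-Wunsch optimal global alignment under linear gap scoring
#' (defaults match = 1, mismatch = 0, gap = -1, the identity scale).
#' Identity is the number of matched columns divided by the total number
#' of alignment columns (gaps included).
#'
#' @param a,b Non-empty sequences.
#' @param match,mismatch,gap Scoring parameters.
#' @param return_alignment If `TRUE`, also return the aligned strings and
#'   score.
#' @return Fractional identity in `[0, 1]`, or a list when
#'   `return_alignment = TRUE` (`identity`, `score`, `alignment` = 2
#'   strings).
#' @export
global_align_identity <- function(a, b, match = 1, mismatch = 0, gap = -1,
                                  return_alignment = FALSE) {
  if (!nzchar(a) || !nzchar(b) || is.na(a) || is.na(b))
    stop("sequences must be non-empty", call. = FALSE)
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n)
  F[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(y == x[i], match, mismatch)
    row_prev <- F[i, ]
    row_cur <- F[i + 1L, ]
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- max(row_prev[j] + sub[j],
                             row_prev[j + 1L] + gap,
                             row_cur[j] + gap)
    }
    F[i + 1L, ] <- row_cur
  }
  # traceback: prefer diagonal, then up, then left
  i <- n; j <- m
  ax <- character(0); ay <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        F[i + 1L, j + 1L] ==
          F[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      ax <- c(x[i], ax); ay <- c(y[j], ay); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      ax <- c(x[i], ax); ay <- c("-", ay); i <- i - 1L
    } else {
      ax <- c("-", ax); ay <- c(y[j], ay); j <- j - 1L
    }
  }
  ident <- sum(ax == ay & ax != "-") / length(ax)
  if (return_alignment)
    list(identity = ident, score = F[n + 1L, m + 1L],
         alignment = c(paste(ax, collapse = ""), paste(ay, collapse = "")))
  else ident
}

#' Pairwise identity distance matrix
#'
#' Symmetric matrix of d = 1 - fractional identity over all sequence pairs.
#'
#' @param seqs Named character vector of >= 2 sequences (unique names).
#' @param ... Scoring parameters passed to [global_align_identity()].
#' @return Symmetric numeric matrix with zero diagonal and dimnames.
#' @export
distance_matrix <- function(seqs, ...) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids", call. = FALSE)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - global_align_identity(seqs[[i]], seqs[[j]], ...)
    }
  }
  d
}

.check_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("D must be a square numeric matrix", call. = FALSE)
  if (nrow(D) < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("L", seq_len(nrow(D)))
  }
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0) || any(D < 0) ||
      any(!is.finite(D)))
    stop("invalid distance matrix: must be symmetric, nonnegative, ",
         "finite, with zero diagonal", call. = FALSE)
  D
}

#' UPGMA hierarchical clustering
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters, with inter-cluster distance the
#' size-weighted average of member distances. Node height = merge distance
#' / 2, which makes every output tree ultrametric (all root-to-leaf path
#' lengths equal). Tied merges are resolved by the lexicographically
#' smallest (representative label, representative label) pair, where a
#' cluster is represented by its smallest leaf label.
#'
#' @param D Symmetric distance matrix with zero diagonal (labels taken
#'   from rownames).
#' @return Object of class `upgma_tree`: list with hclust-style `merge`,
#'   `merge_distance`, `node_height` (= merge_distance / 2), `labels` and
#'   `order`. See [as.hclust.upgma_tree()], [to_newick()], [cut_groups()].
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(D))  # ((A:1,B:1):1,C:2);
#' @export
upgma <- function(D) {
  D <- .check_distance_matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  # active clusters: id (negative leaf / positive merge), size, rep label
  work <- D
  cl_id <- -seq_len(n)
  cl_size <- rep(1L, n)
  cl_rep <- labels
  merge <- matrix(0L, n - 1L, 2L)
  merge_distance <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(cl_id)
    dmin <- Inf; best <- NULL
    eps <- 1e-15
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        rep_pair <- sort(c(cl_rep[i], cl_rep[j]))
        if (work[i, j] < dmin - eps) {
          dmin <- work[i, j]
          best <- list(i = i, j = j, rep = rep_pair)
        } else if (work[i, j] <= dmin + eps &&
                   (rep_pair[1L] < best$rep[1L] ||
                    (rep_pair[1L] == best$rep[1L] &&
                     rep_pair[2L] < best$rep[2L]))) {
          best <- list(i = i, j = j, rep = rep_pair)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- .upgma_order_pair(cl_id[i], cl_id[j], cl_rep[i], cl_rep[j])
    merge_distance[step] <- work[i, j]
    # size-weighted average distance to the new cluster
    newd <- (cl_size[i] * work[i, ] + cl_size[j] * work[j, ]) /
      (cl_size[i] + cl_size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    work <- rbind(cbind(work[keep, keep, drop = FALSE], newd[keep]),
                  c(newd[keep], 0))
    cl_id <- c(cl_id[keep], step)
    cl_size <- c(cl_size[keep], cl_size[i] + cl_size[j])
    cl_rep <- c(cl_rep[keep], min(cl_rep[i], cl_rep[j]))
  }
  tree <- structure(list(merge = merge,
                         merge_distance = merge_distance,
                         node_height = merge_distance / 2,
                         labels = labels),
                    class = "upgma_tree")
  tree$order <- .upgma_leaf_order(tree)
  tree
}

# children ordered so the lexicographically smaller representative comes first
.upgma_order_pair <- function(id_i, id_j, rep_i, rep_j) {
  if (rep_i <= rep_j) c(id_i, id_j) else c(id_j, id_i)
}

.upgma_leaf_order <- function(tree) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(tree$merge[node, 1L]), rec(tree$merge[node, 2L]))
  }
  rec(nrow(tree$merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.6g\n",
              length(x$labels), max(x$node_height)))
  invisible(x)
}

#' Convert a UPGMA tree to an hclust object
#'
#' @param x A `upgma_tree`.
#' @param ... Ignored.
#' @return An object of class `hclust` (heights are merge distances).
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$merge_distance,
                 order = x$order, labels = x$labels,
                 method = "average", call = match.call(),
                 dist.method = "identity"),
            class = "hclust")
}

#' Serialize a UPGMA tree to Newick
#'
#' Branch lengths are parent node height minus child node height (leaves
#' at height 0), so root-to-leaf path lengths all equal the root height.
#'
#' @param tree A `upgma_tree`.
#' @param digits Significant digits for branch lengths.
#' @return Newick string, rooted, terminated by ";".
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "upgma_tree"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  rec <- function(node, parent_h) {
    if (node < 0L)
      return(paste0(tree$labels[-node], ":", fmt(parent_h)))
    h <- tree$node_height[node]
    paste0("(", rec(tree$merge[node, 1L], h), ",",
           rec(tree$merge[node, 2L], h), "):", fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$node_height[root]
  paste0("(", rec(tree$merge[root, 1L], h), ",",
         rec(tree$merge[root, 2L], h), ");")
}

#' Cut a UPGMA tree into k groups
#'
#' Removes the k - 1 highest merges, yielding k groups (k = 1 gives one
#' group, k = n singletons). Deterministic given the tree's fixed merge
#' order.
#'
#' @param tree A `upgma_tree`.
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Named integer vector of group memberships (1..k) per leaf.
#' @export
cut_groups <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop("k must be in [1, n leaves]", call. = FALSE)
  stats::cutree(as.hclust(tree), k = as.integer(k))
}

#' Ultrametric (cophenetic) distances implied by a UPGMA tree
#'
#' @param tree A `upgma_tree`.
#' @return Symmetric matrix of tree path distances between leaves (twice
#'   the height of the lowest common ancestor).
#' @export
tree_cophenetic <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  as.matrix(stats::cophenetic(as.hclust(tree)))
}
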