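#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}; with
#' rows normalized to 1 this is half the L1 distance. Dissimilarity is stored
#' in [0, 1]; the percent-similarity view used in dendrogram reports is
#' \eqn{100 (1 - d)} (see [similarity_percent()]).
#'
#' @param m an \code{abundance_matrix} or plain non-negative matrix with
#'   sample ids as row names.
#' @return a \code{dist} object labelled with the sample ids.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  stats::as.dist(d)
}

#' Percent-similarity view of a dissimilarity
#' @param d \code{dist} or numeric dissimilarity values in [0, 1].
#' @return \eqn{100 (1 - d)}.
#' @export
similarity_percent <- function(d) 100 * (1 - as.numeric(d))

#' Group-average (UPGMA) agglomerative clustering
#'
#' At each step the pair of clusters with the smallest average cross-pair
#' dissimilarity is merged; the inter-cluster distance is the unweighted mean
#' over all cross pairs (recomputed by the Lance-Williams size-weighted
#' update). Ties in the minimum are broken deterministically towards the
#' lexicographically smallest pair of member labels. Group-average merge
#' heights are never decreasing.
#'
#' @param d a \code{dist} with labels (e.g. from [bray_curtis()]).
#' @return an object of class \code{hclust} (merge, height, order, labels),
#'   so \code{plot()}, \code{cutree()} and \code{as.dendrogram()} apply.
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  labels <- rownames(dm) %||% as.character(seq_len(n))
  if (n < 2) stop("need at least two samples", call. = FALSE)
  size <- rep(1L, n)
  active <- seq_len(n)
  node <- -seq_len(n)              # hclust convention: negatives = leaves
  minlab <- labels                 # lexicographically smallest member label
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(active)) for (b in seq_along(active)) if (b > a) {
      i <- active[a]; j <- active[b]
      dij <- dm[i, j]
      key <- sort(c(minlab[i], minlab[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- best$d
    # average-linkage update: new cluster kept in slot i
    for (k in setdiff(active, c(i, j))) {
      dm[i, k] <- dm[k, i] <-
        (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    node[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
    active <- setdiff(active, j)
  }
  out <- structure(list(merge = merge, height = height,
                        order = upgma_order(merge, n),
                        labels = labels, method = "average",
                        call = match.call(),
                        dist.method = "bray-curtis"),
                   class = "hclust")
  out
}

# leaf ordering for plotting: left-to-right traversal of the merge tree
upgma_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Cut a dendrogram at a percent-similarity threshold
#'
#' Clusters are the maximal subtrees all of whose internal merge heights are
#' at most \eqn{(100 - \mathrm{threshold})/100}; singletons are allowed.
#' Cluster ids are numbered by first appearance in label order.
#'
#' @param tree an \code{hclust} (e.g. from [upgma()]).
#' @param similarity_threshold percent similarity in [0, 100] (e.g. 70 for
#'   the conventional >= 70-percent cut).
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(tree, similarity_threshold) {
  stopifnot(inherits(tree, "hclust"),
            similarity_threshold >= 0, similarity_threshold <= 100)
  h_cut <- (100 - similarity_threshold) / 100
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  leaf_of_node <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    members <- unlist(lapply(tree$merge[s, ], function(x)
      if (x < 0) -x else leaf_of_node[[x]]))
    leaf_of_node[[s]] <- members
    if (tree$height[s] <= h_cut) {
      r <- find(members[1])
      for (m in members[-1]) parent[find(m)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  setNames(ids, tree$labels)
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Minimizes Kruskal stress-1 over a monotone regression of configuration
#' distances on dissimilarity ranks (via \code{vegan::monoMDS}). The first
#' start is the metric (principal-coordinates) configuration; the remaining
#' \code{restarts - 1} are seeded random configurations, and the lowest-stress
#' solution is kept. Coordinates are centred at the origin.
#'
#' @param d a \code{dist} of dissimilarities, n >= 3.
#' @param k embedding dimension (default 2).
#' @param restarts number of starts (default 50).
#' @param maxit iteration cap per start (default 300).
#' @param seed RNG seed for the random starts (default 42).
#' @return object of class \code{arisa_nmds}: list with \code{points}
#'   (n x k matrix), \code{stress} (Kruskal stress-1), \code{converged},
#'   \code{restarts}, \code{seed}.
#' @export
nmds <- function(d, k = 2, restarts = 50, maxit = 300, seed = 42) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) stop("need at least 3 samples", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- if (r == 1L) {
      vegan::monoMDS(d, k = k, maxit = maxit)
    } else {
      vegan::monoMDS(d, y = matrix(rnorm(n * k), n, k), k = k, maxit = maxit)
    }
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("MDS", seq_len(k))
  converged <- is.null(best$icause) || best$icause != 1L  # 1 = maxit reached
  if (!converged)
    warning("nMDS did not meet its convergence criteria; best-so-far returned")
  structure(list(points = pts, stress = best$stress, converged = converged,
                 restarts = restarts, seed = seed),
            class = "arisa_nmds")
}

#' @export
print.arisa_nmds <- function(x, ...) {
  cat(sprintf(
    "nMDS ordination: %d samples in %d dimensions\nKruskal stress-1 = %.4f (%d restarts, seed %d)%s\n",
    nrow(x$points), ncol(x$points), x$stress, x$restarts, x$seed,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
plot.arisa_nmds <- function(x, ...) {
  graphics::plot(x$points, asp = 1, ...)
  graphics::text(x$points, labels = rownames(x$points), pos = 3, cex = 0.7)
  invisible(x)
}

#' Export a dendrogram as Newick plus a merge-height sidecar
#'
#' Newick branch lengths carry height differences between nested merges
#' (leaf-to-parent = parent height); because Newick alone cannot encode
#' absolute merge heights, they are written to a JSON sidecar
#' (\code{<path>.heights.json}).
#'
#' @param tree an \code{hclust}.
#' @param path output Newick path.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  phy$edge.length <- phy$edge.length * 2   # as.phylo halves hclust heights
  ape::write.tree(phy, file = path)
  jsonlite::write_json(
    list(labels = tree$labels, merge = tree$merge, height = tree$height),
    paste0(path, ".heights.json"), digits = NA, auto_unbox = FALSE)
  invisible(path)
}
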