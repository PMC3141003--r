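## Cluster-3.0-style agglomerative clustering of specimens on their
## differential-expression profiles. Distances are correlation-based
## (centered Pearson or uncentered), linkage is complete, average, or
## centroid; centroid linkage recomputes the correlation distance between
## mean cluster profiles. Ties are broken deterministically by specimen
## order, so the dendrogram is reproducible.

cor_distance <- function(X, distance) {
  p <- ncol(X)
  D <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- 1 - profile_similarity(X[, i], X[, j], distance)
  }
  D
}

profile_similarity <- function(x, y, distance) {
  if (distance == "uncentered") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      warning("constant zero profile; correlation defined as 0",
              call. = FALSE)
      return(0)
    }
    sum(x * y) / (nx * ny)
  } else {
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant profile (zero variance); correlation defined as 0",
              call. = FALSE)
      return(0)
    }
    cor(x, y)
  }
}

#' Hierarchical clustering of specimens
#'
#' @param profiles matrix genes x specimens (typically the per-individual M
#'   profiles restricted to batch-called genes).
#' @param distance `"pearson"` (1 - centered correlation) or `"uncentered"`
#'   (1 - uncentered correlation).
#' @param linkage `"complete"`, `"average"`, or `"centroid"` (correlation
#'   distance between mean cluster profiles).
#' @return An object of class `specimen_dendrogram` (with `merge`, `height`,
#'   `labels`, `order` in `hclust` layout); convert with
#'   [dendrogram_newick()] or `stats::as.hclust`.
#' @export
cluster_specimens <- function(profiles,
                              distance = c("pearson", "uncentered"),
                              linkage = c("complete", "average", "centroid")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  p <- ncol(profiles)
  if (p < 3) stop_arg("need at least 3 specimens")
  if (nrow(profiles) < 2) stop_arg("need at least 2 genes")
  labels <- colnames(profiles) %||% as.character(seq_len(p))
  D <- cor_distance(profiles, distance)
  active <- as.list(seq_len(p))            # member leaf indices per cluster
  ids <- -seq_len(p)                       # hclust coding: leaves negative
  sizes <- rep(1L, p)
  centroids <- profiles
  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)
  cur <- D
  alive <- rep(TRUE, p)
  idx <- seq_len(p)
  for (step in seq_len(p - 1)) {
    ai <- which(alive)
    best <- c(NA, NA); bd <- Inf
    for (u in ai) for (v in ai) {
      if (v <= u) next
      if (cur[u, v] < bd - 1e-12) { bd <- cur[u, v]; best <- c(u, v) }
    }
    u <- best[1]; v <- best[2]
    merge[step, ] <- sort(c(ids[u], ids[v]))
    height[step] <- bd
    ## merge v into u
    newmem <- c(active[[u]], active[[v]])
    active[[u]] <- newmem
    sizes_u <- sizes[u]; sizes_v <- sizes[v]
    if (linkage == "centroid") {
      centroids[, u] <- rowMeans(profiles[, newmem, drop = FALSE])
    }
    for (w in ai) {
      if (w == u || w == v) next
      cur[u, w] <- cur[w, u] <- switch(
        linkage,
        complete = max(cur[u, w], cur[v, w]),
        average = (sizes_u * cur[u, w] + sizes_v * cur[v, w]) /
          (sizes_u + sizes_v),
        centroid = 1 - profile_similarity(centroids[, u], centroids[, w],
                                          distance))
    }
    sizes[u] <- sizes_u + sizes_v
    alive[v] <- FALSE
    ids[u] <- step
  }
  ord <- dendrogram_order(merge)
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord, method = linkage, distance = distance,
                 call = match.call(), dist.method = distance),
            class = c("specimen_dendrogram", "hclust"))
}

dendrogram_order <- function(merge) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(nrow(merge))
}

#' Export a specimen dendrogram as a Newick string
#'
#' @param dendro a `specimen_dendrogram`.
#' @param path optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dendro))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
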