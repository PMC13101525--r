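#' Build a Spearman co-occurrence network
#'
#' For every retained taxon pair, computes Spearman's rho (average ranks
#' on ties) and its p-value, and keeps an edge iff \eqn{|\rho| \ge}
#' `r_threshold` and \eqn{p \le} `p_threshold` — the thresholding scheme
#' standard in microbial network studies (defaults |rho| >= 0.75,
#' p <= 0.01). The correlation sign is stored as an edge attribute so
#' reports can state the positive-edge fraction rather than assume it.
#' p-values use the t-distribution approximation for 10 or more samples
#' and the exact null distribution (via [stats::cor.test()]) below that.
#' Taxa observed in fewer than `min_prevalence` of samples are dropped
#' before correlation; constant (zero-variance) taxa are excluded with a
#' warning and can never carry an edge.
#'
#' @param x abundance matrix (samples x taxa), at least 4 samples.
#' @param r_threshold minimum absolute Spearman rho (default 0.75).
#' @param p_threshold maximum correlation p-value (default 0.01).
#' @param min_prevalence minimum fraction of samples in which a taxon must
#'   be detected (abundance > 0) to enter the network (default 0).
#' @param p_adjust_method optional multiple-testing correction applied to
#'   the pairwise p-values before thresholding (e.g. `"BH"`); default
#'   `"none"`, matching the raw-threshold convention.
#' @param families optional named character vector mapping taxon id to a
#'   family-level annotation, used by [high_weight_edges()].
#' @return an object of class `cooccur_net`: list with `nodes`, `edges`
#'   (data.frame `source`, `target`, `rho`, `p`, `sign`), `families`,
#'   `thresholds` and `excluded` (constant taxa).
#' @export
correlation_network <- function(x, r_threshold = 0.75, p_threshold = 0.01,
                                min_prevalence = 0, p_adjust_method = "none",
                                families = NULL) {
  validate_abundance(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples to estimate correlations")
  prev <- colMeans(x > 0)
  x <- x[, prev >= min_prevalence, drop = FALSE]
  constant <- colnames(x)[apply(x, 2, function(v) length(unique(v)) == 1)]
  if (length(constant) > 0) {
    warning("excluding constant taxa: ", paste(constant, collapse = ", "))
    x <- x[, setdiff(colnames(x), constant), drop = FALSE]
  }
  taxa <- colnames(x)
  p_taxa <- length(taxa)
  edges <- data.frame(source = character(0), target = character(0),
                      rho = numeric(0), p = numeric(0), sign = integer(0),
                      stringsAsFactors = FALSE)
  if (p_taxa >= 2) {
    rho <- stats::cor(x, method = "spearman")
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    rho_v <- rho[upper.tri(rho)]
    if (n >= 10) {
      tstat <- rho_v * sqrt((n - 2) / pmax(1 - rho_v^2, .Machine$double.eps))
      pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
      pv[abs(rho_v) >= 1] <- 0
    } else {
      pv <- vapply(seq_len(nrow(idx)), function(k) {
        suppressWarnings(stats::cor.test(x[, idx[k, 1]], x[, idx[k, 2]],
                                         method = "spearman")$p.value)
      }, numeric(1))
    }
    pv <- stats::p.adjust(pv, method = p_adjust_method)
    keep <- abs(rho_v) >= r_threshold & pv <= p_threshold
    if (any(keep)) {
      a <- taxa[idx[keep, 1]]; b <- taxa[idx[keep, 2]]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      edges <- data.frame(source = a, target = b, rho = rho_v[keep],
                          p = pv[keep], sign = ifelse(rho_v[keep] >= 0, 1L, -1L),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$source, edges$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = taxa, edges = edges, families = families,
                 thresholds = list(r = r_threshold, p = p_threshold,
                                   min_prevalence = min_prevalence,
                                   p_adjust = p_adjust_method),
                 excluded = constant),
            class = "cooccur_net")
}

#' Construct a network directly from an edge list
#'
#' Used by [read_edge_list()] and by tests that need a graph with known
#' topology; thresholds are recorded as given, not re-checked.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `rho`, `p` (defaults 1 and 0).
#' @param families optional named family annotation.
#' @param thresholds optional list recorded in the object.
#' @return a `cooccur_net` object.
#' @export
as_cooccur_net <- function(nodes, edges, families = NULL, thresholds = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  nr <- nrow(edges)
  if (is.null(edges$rho)) edges$rho <- rep(1, nr)
  if (is.null(edges$p)) edges$p <- rep(0, nr)
  if (is.null(edges$sign)) edges$sign <- ifelse(edges$rho >= 0, 1L, -1L)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (!all(c(edges$source, edges$target) %in% nodes))
      stop("edge endpoint not in node set")
    swap <- edges$source > edges$target
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
    if (anyDuplicated(edges[, c("source", "target")]))
      stop("parallel edges are not allowed")
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes,
                 edges = edges[, c("source", "target", "rho", "p", "sign")],
                 families = families, thresholds = thresholds, excluded = character(0)),
            class = "cooccur_net")
}

#' @export
print.cooccur_net <- function(x, ...) {
  m <- network_metrics(x, allow_small = TRUE)
  cat("Spearman co-occurrence network\n")
  cat(sprintf("  nodes: %d   edges: %d\n", m$n_nodes, m$n_edges))
  if (m$n_nodes >= 2)
    cat(sprintf("  avg degree: %.2f   density: %.3f   avg clustering: %.3f\n",
                m$avg_degree, m$density, m$avg_clustering))
  if (nrow(x$edges) > 0)
    cat(sprintf("  positive edges: %.1f%%\n", 100 * mean(x$edges$sign > 0)))
  if (!is.null(x$thresholds))
    cat(sprintf("  thresholds: |rho| >= %s, p <= %s\n",
                format(x$thresholds$r), format(x$thresholds$p)))
  invisible(x)
}

## dense adjacency matrix of a cooccur_net (unweighted, symmetric)
adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$source, net$nodes)
    j <- match(net$edges$target, net$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

## connected component labels from an adjacency matrix (BFS)
components_of <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] == 1L & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## unweighted shortest-path lengths from node s (Inf if unreachable)
bfs_dist <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] == 1L & is.infinite(dist))
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  dist
}

## mean inverse shortest-path length over unordered pairs; disconnected
## pairs contribute 0, so the value is finite and lies in [0, 1]
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  tot <- 0
  for (s in seq_len(n - 1)) {
    dist <- bfs_dist(A, s)
    tot <- tot + sum(1 / dist[(s + 1):n][is.finite(dist[(s + 1):n])])
  }
  tot / (n * (n - 1) / 2)
}

#' Basic topology metrics of a co-occurrence network
#'
#' Average degree \eqn{2E/N}, density \eqn{2E/(N(N-1))} and the mean local
#' clustering coefficient \eqn{C_i = 2T_i / (k_i (k_i - 1))} (0 for nodes
#' with degree < 2), where \eqn{T_i} counts triangles through node i.
#'
#' @param net a `cooccur_net`.
#' @param allow_small internal: return partial metrics for N < 2 instead
#'   of erroring (used by the print method).
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `density`,
#'   `avg_clustering`.
#' @export
network_metrics <- function(net, allow_small = FALSE) {
  A <- adjacency(net)
  n <- nrow(A)
  e <- nrow(net$edges)
  if (n < 2) {
    if (allow_small)
      return(list(n_nodes = n, n_edges = e, avg_degree = NA_real_,
                  density = NA_real_, avg_clustering = NA_real_))
    stop("density undefined for networks with fewer than 2 nodes")
  }
  deg <- rowSums(A)
  A2 <- A %*% A
  tri <- diag(A2 %*% A) / 2          # triangles through each node
  denom <- deg * (deg - 1) / 2
  ci <- ifelse(deg >= 2, tri / denom, 0)
  list(n_nodes = n, n_edges = e,
       avg_degree = 2 * e / n,
       density = 2 * e / (n * (n - 1)),
       avg_clustering = mean(ci))
}

#' Network robustness under random node removal
#'
#' Per repetition, removes `floor(removal_fraction * N)` uniformly chosen
#' nodes and records the fraction of the *surviving* nodes that sit in the
#' largest connected component of the surviving subgraph; returns the mean
#' over `n_reps` repetitions (defaults: half the nodes removed, 100
#' repetitions — the convention of microbial network stability studies).
#' Isolated survivors count as singleton components.
#'
#' @param net a `cooccur_net` with at least 2 nodes.
#' @param removal_fraction fraction of nodes removed, in (0, 1).
#' @param n_reps number of random repetitions.
#' @param seed integer seed.
#' @return mean largest-component fraction among survivors, in [0, 1].
#' @export
robustness <- function(net, removal_fraction = 0.5, n_reps = 100, seed = NULL) {
  A <- adjacency(net)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  if (removal_fraction <= 0 || removal_fraction >= 1)
    stop("removal_fraction must lie strictly between 0 and 1")
  n_remove <- floor(removal_fraction * n)
  if (n - n_remove < 1) stop("removal leaves no survivors")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n_reps), function(i) {
    survivors <- sort(sample.int(n, n - n_remove))
    As <- A[survivors, survivors, drop = FALSE]
    comp <- components_of(As)
    max(tabulate(comp)) / length(survivors)
  }, numeric(1))
  mean(vals)
}

#' Global efficiency and node vulnerability
#'
#' Global efficiency is the mean inverse shortest-path length over
#' unordered node pairs (disconnected pairs contribute 0). The
#' vulnerability of node i is its relative contribution to global
#' efficiency, \eqn{V_i = (E_{glob}(G) - E_{glob}(G - i)) / E_{glob}(G)},
#' and the network's vulnerability is the maximum over nodes — high when
#' connectivity hinges on a few hubs. An edgeless network has efficiency
#' 0 and its vulnerability is defined as 0 with a warning.
#'
#' @param net a `cooccur_net` with at least 3 nodes.
#' @return list with `global_efficiency`, `per_node_vulnerability` (named),
#'   `vulnerability`.
#' @export
vulnerability <- function(net) {
  A <- adjacency(net)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 nodes")
  e_full <- global_efficiency(A)
  if (e_full == 0) {
    warning("edgeless network: global efficiency 0, vulnerability defined as 0")
    v <- stats::setNames(rep(0, n), net$nodes)
    return(list(global_efficiency = 0, per_node_vulnerability = v,
                vulnerability = 0))
  }
  v <- vapply(seq_len(n), function(i) {
    (e_full - global_efficiency(A[-i, -i, drop = FALSE])) / e_full
  }, numeric(1))
  names(v) <- net$nodes
  list(global_efficiency = e_full, per_node_vulnerability = v,
       vulnerability = max(v))
}

#' Extract high-weight edges with family-pair annotation
#'
#' Returns the edges with rho strictly above `threshold` (default 0.9, the
#' usual cut for "strong" interactions), annotated with the family of each
#' endpoint when a family map is attached to the network, plus per
#' family-pair counts suitable for heatmap export.
#'
#' @param net a `cooccur_net`.
#' @param threshold minimum rho, strict (default 0.9).
#' @return list with `edges` (data.frame `source`, `target`, `rho`, `p`,
#'   `family_source`, `family_target`) and `family_pair_counts`
#'   (data.frame `family_a`, `family_b`, `count`; `family_a <= family_b`).
#' @export
high_weight_edges <- function(net, threshold = 0.9) {
  ed <- net$edges[net$edges$rho > threshold, , drop = FALSE]
  fam <- net$families
  getfam <- function(id) {
    if (is.null(fam)) rep(NA_character_, length(id))
    else unname(fam[id])
  }
  ed$family_source <- getfam(ed$source)
  ed$family_target <- getfam(ed$target)
  rownames(ed) <- NULL
  if (nrow(ed) > 0) {
    fa <- pmin(ed$family_source, ed$family_target)
    fb <- pmax(ed$family_source, ed$family_target)
    key <- paste(fa, fb, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- data.frame(family_a = vapply(parts, `[`, "", 1),
                         family_b = vapply(parts, `[`, "", 2),
                         count = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    counts <- data.frame(family_a = character(0), family_b = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  }
  list(edges = ed, family_pair_counts = counts)
}

#' Write a network edge list as TSV
#'
#' Columns `source`, `target`, `rho`, `p`, `sign` plus family annotations
#' when available; one row per undirected edge with `source < target`
#' lexicographically. The paired reader is [read_edge_list()].
#'
#' @param net a `cooccur_net`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- net$edges
  if (!is.null(net$families)) {
    ed$family_source <- unname(net$families[ed$source])
    ed$family_target <- unname(net$families[ed$target])
  }
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' @param path TSV edge-list path.
#' @param nodes optional full node set (isolated nodes are not recoverable
#'   from an edge list alone); defaults to the nodes seen on edges.
#' @return a `cooccur_net`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  ed <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(ed) > 0 && !all(c("source", "target") %in% names(ed)))
    stop("edge list needs 'source' and 'target' columns")
  families <- NULL
  if ("family_source" %in% names(ed) && nrow(ed) > 0) {
    families <- c(stats::setNames(ed$family_source, ed$source),
                  stats::setNames(ed$family_target, ed$target))
    families <- families[!duplicated(names(families))]
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(ed$source, ed$target)))
  as_cooccur_net(nodes, ed[, intersect(c("source", "target", "rho", "p", "sign"),
                                       names(ed)), drop = FALSE],
                 families = families)
}
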