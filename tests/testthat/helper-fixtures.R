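# Shared fixtures, all generated in code.

random_table <- function(n_samples, n_taxa, seed, lambda = 8) {
  set.seed(seed)
  x <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  dimnames(x) <- list(paste0("s", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  x
}

# network with given topology; rho/p filled with placeholders
graph_net <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  as_cooccur_net(nodes, edges)
}

complete_net <- function(n) {
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  graph_net(data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]]),
            nodes)
}

edgeless_net <- function(n) {
  as_cooccur_net(sprintf("v%02d", seq_len(n)),
                 data.frame(source = character(0), target = character(0)))
}

path_net <- function(labels = c("A", "B", "C")) {
  graph_net(data.frame(source = labels[-length(labels)],
                       target = labels[-1]), labels)
}

star_net <- function(n_leaves = 8) {
  nodes <- c("hub", sprintf("leaf%02d", seq_len(n_leaves)))
  graph_net(data.frame(source = rep("hub", n_leaves), target = nodes[-1]),
            nodes)
}

cycle_net <- function(n) {
  nodes <- sprintf("v%02d", seq_len(n))
  graph_net(data.frame(source = nodes, target = nodes[c(2:n, 1)]), nodes)
}

er_net <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p_edge
  graph_net(data.frame(source = nodes[idx[keep, 1]],
                       target = nodes[idx[keep, 2]]), nodes)
}

to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

euclid_dm <- function(n, k = 4, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * k), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}
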