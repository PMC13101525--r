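#' Per-sample alpha diversity
#'
#' Computes richness (taxa with abundance > 0), Shannon entropy
#' \eqn{H = -\sum q_k \ln q_k} on relative abundances, Pielou evenness
#' \eqn{J = H / \ln S} (defined as 0 for samples with fewer than two taxa,
#' so the table stays total), and optionally Faith's phylogenetic
#' diversity. PD follows the root-inclusive convention of the common
#' amplicon toolchains: the total branch length of the minimal subtree
#' connecting the present leaves *and the root*.
#'
#' @param x abundance matrix (samples x taxa); counts or relative.
#' @param tree optional rooted tree (from [read_newick()]) whose leaves
#'   cover all taxa observed with positive abundance.
#' @return data.frame with one row per sample and columns `richness`,
#'   `shannon`, `pielou` and, if a tree is given, `pd`.
#' @export
#' @examples
#' x <- matrix(c(5, 5, 0, 9, 1, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' alpha_diversity(x)
alpha_diversity <- function(x, tree = NULL) {
  validate_abundance(x)
  if (nrow(x) == 0) stop("empty abundance table")
  rel <- relative_abundance(x)
  richness <- rowSums(x > 0)
  shannon <- apply(rel, 1, function(q) {
    q <- q[q > 0]
    if (length(q) == 0) 0 else -sum(q * log(q))
  })
  pielou <- ifelse(richness >= 2, shannon / log(richness), 0)
  out <- data.frame(richness = as.numeric(richness), shannon = shannon,
                    pielou = pielou, row.names = rownames(x))
  if (!is.null(tree)) {
    out$pd <- vapply(rownames(x), function(s) {
      faith_pd(tree, colnames(x)[x[s, ] > 0])
    }, numeric(1))
  }
  out
}

#' Pairwise beta diversity
#'
#' Bray-Curtis on abundances,
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' or binary Jaccard on presence/absence,
#' \eqn{d_{ij} = 1 - |A_i \cap A_j| / |A_i \cup A_j|}. A pair in which
#' both samples are all-zero is given distance 0 with a warning.
#'
#' @param x abundance matrix (samples x taxa).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
beta_diversity <- function(x, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  validate_abundance(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  if (metric == "jaccard") x <- (x > 0) * 1
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (metric == "bray_curtis") {
        den <- sum(x[i, ] + x[j, ])
        val <- if (den == 0) NA_real_ else sum(abs(x[i, ] - x[j, ])) / den
      } else {
        un <- sum(x[i, ] | x[j, ])
        val <- if (un == 0) NA_real_ else 1 - sum(x[i, ] & x[j, ]) / un
      }
      if (is.na(val)) {
        if (!warned) {
          warning("pair of all-zero samples; distance set to 0")
          warned <- TRUE
        }
        val <- 0
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical (metric) MDS: Gower double-centering of \eqn{-d^2/2} followed
#' by a symmetric eigendecomposition, with coordinates scaled by the square
#' root of the eigenvalue. Axes belonging to negative eigenvalues are
#' dropped but the eigenvalues themselves are reported — no Cailliez or
#' Lingoes correction is applied, so non-Euclidean input is visible rather
#' than silently patched. Proportion explained is computed over the
#' positive eigenvalues only.
#'
#' @param d symmetric distance matrix (e.g. from [beta_diversity()]).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending) and `proportion_explained` (per retained axis).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  ## cmdscale warns when negative eigenvalues force fewer axes; that is
  ## expected for non-Euclidean input and reported via `eigenvalues`
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > .Machine$double.eps * max(abs(eig)) * n
  k <- sum(pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[seq_len(k)] / sum(eig[pos]))
}
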