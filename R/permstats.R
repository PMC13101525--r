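## Permutation statistics (ANOSIM, PERMANOVA, Mantel), implemented from
## their definitions. All three share the same machinery: an observed
## statistic, a null built by permuting sample labels (jointly over rows
## and columns of the distance matrix), and the unbiased permutation
## p-value (1 + #{null >= observed}) / (1 + n_permutations), which can
## never be exactly zero. When the requested permutation count reaches
## the number of distinct label assignments, the null is enumerated
## exhaustively instead and the p-value is the exact tail fraction.

check_dm_groups <- function(d, groups) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups must cover every sample")
  if (anyNA(groups)) stop("group label missing for some samples")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 samples (singleton: ",
                         paste(names(tab)[tab < 2], collapse = ", "), ")")
  list(d = d, groups = groups)
}

## number of distinct assignments of the multiset of labels to positions
n_distinct_assignments <- function(groups) {
  tab <- table(groups)
  exp(lgamma(length(groups) + 1) - sum(lgamma(tab + 1)))
}

## all distinct label vectors for the multiset `groups` (small n only)
enumerate_assignments <- function(groups) {
  labs <- sort(unique(groups))
  rec <- function(remaining, counts) {
    if (length(remaining) == 0) return(list(character(0)))
    out <- list()
    for (l in labs) {
      if (counts[[l]] > 0) {
        counts2 <- counts
        counts2[[l]] <- counts2[[l]] - 1
        for (tail in rec(remaining[-1], counts2))
          out[[length(out) + 1]] <- c(l, tail)
      }
    }
    out
  }
  counts <- as.list(table(groups))
  rec(seq_along(groups), counts)
}

perm_pvalue <- function(stat_fun, groups, n_perm, seed) {
  obs <- stat_fun(groups)
  n_exact <- n_distinct_assignments(groups)
  if (is.finite(n_exact) && n_perm >= n_exact && n_exact <= 1e5) {
    all_assign <- enumerate_assignments(groups)
    null <- vapply(all_assign, stat_fun, numeric(1))
    p <- mean(null >= obs - 1e-12)   # observed assignment is in the set
    return(list(statistic = obs, p_value = p, n_permutations = length(null),
                exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat_fun(sample(groups)),
                 numeric(1))
  p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
  list(statistic = obs, p_value = p, n_permutations = n_perm,
       exhaustive = FALSE)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all between-sample dissimilarities (average ranks on ties) and
#' contrasts mean between-group and mean within-group ranks:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = n(n-1)/2}.
#' R near 1 means complete group separation, near 0 none. Significance
#' by permutation of sample labels; for small designs where `n_perm`
#' covers all distinct label assignments the null is enumerated exactly.
#'
#' @param d distance matrix (samples x samples).
#' @param groups group label per sample (named by sample id, or in row
#'   order of `d`).
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed for the permutation draw.
#' @return list with `statistic_name = "ANOSIM_R"`, `statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
anosim_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  cg <- check_dm_groups(d, groups)
  d <- cg$d
  n <- nrow(d)
  lt <- lower.tri(d)
  r <- rank(d[lt])          # average ranks on ties
  M <- n * (n - 1) / 2
  ii <- row(d)[lt]; jj <- col(d)[lt]
  stat_fun <- function(g) {
    within <- g[ii] == g[jj]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  res <- perm_pvalue(stat_fun, cg$groups, n_perm, seed)
  list(statistic_name = "ANOSIM_R", statistic = res$statistic,
       p_value = res$p_value, n_permutations = res$n_permutations,
       exhaustive = res$exhaustive, seed = seed)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Distance-based ANOVA decomposition:
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n},
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' pseudo-F \eqn{= (SS_B/(a-1)) / (SS_W/(n-a))} and
#' \eqn{R^2 = SS_B / SS_T}. With Euclidean distances on univariate data
#' the pseudo-F equals the classical one-way ANOVA F. Significance by
#' permutation of sample labels (exhaustive for small designs, as in
#' [anosim_test()]).
#'
#' @inheritParams anosim_test
#' @return list with `statistic` (pseudo-F), `r_squared`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  cg <- check_dm_groups(d, groups)
  d <- cg$d
  n <- nrow(d)
  d2 <- d^2
  lt <- lower.tri(d)
  ss_total <- sum(d2[lt]) / n
  ii <- row(d)[lt]; jj <- col(d)[lt]
  d2v <- d2[lt]
  a <- length(unique(cg$groups))
  ss_within_fun <- function(g) {
    within <- g[ii] == g[jj]
    ng <- table(g)
    per_group <- tapply(d2v[within], g[ii][within], sum)
    sum(per_group / as.numeric(ng[names(per_group)]))
  }
  stat_fun <- function(g) {
    ss_within <- ss_within_fun(g)
    ss_between <- ss_total - ss_within
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  res <- perm_pvalue(stat_fun, cg$groups, n_perm, seed)
  ## recompute the R^2 for the observed labelling
  ss_within <- ss_within_fun(cg$groups)
  list(statistic_name = "PERMANOVA_pseudoF", statistic = res$statistic,
       r_squared = (ss_total - ss_within) / ss_total,
       p_value = res$p_value, n_permutations = res$n_permutations,
       exhaustive = res$exhaustive, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) of the two off-diagonal vectors;
#' the null is built by simultaneously permuting rows and columns of the
#' second matrix, which preserves its internal structure.
#'
#' @param d1,d2 distance matrices over the identical sample set, in the
#'   same order (checked via dimnames when present).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `r`, `p_value`, `method`, `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("sample sets/order differ between the two matrices")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt], method = method)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n)
    stats::cor(v1, d2[perm, perm][lt], method = method)
  }, numeric(1))
  p <- (1 + sum(null >= r_obs - 1e-12)) / (1 + n_perm)
  list(r = r_obs, p_value = p, method = method,
       n_permutations = n_perm, seed = seed)
}
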