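## presence matrix: taxa x groups, TRUE iff the taxon passes detection
## (count > 0 in at least min_samples samples of the group)
presence_by_group <- function(x, groups, min_samples = 1) {
  validate_abundance(x)
  if (!is.null(names(groups))) groups <- groups[rownames(x)]
  groups <- as.character(groups)
  if (length(groups) != nrow(x) || anyNA(groups))
    stop("groups must label every sample")
  if (min_samples < 1) stop("detection threshold must be at least 1 sample")
  labs <- unique(groups)
  pres <- sapply(labs, function(g) {
    colSums(x[groups == g, , drop = FALSE] > 0) >= min_samples
  })
  if (is.null(dim(pres))) pres <- matrix(pres, ncol = length(labs),
                                         dimnames = list(colnames(x), labs))
  pres
}

#' Partition taxa into core, accessory and group-specific sets
#'
#' A taxon is "present in group g" when it is detected (count > 0) in at
#' least `min_samples` samples of g (default 1, pooling replicates and
#' timepoints). Core taxa are present in all groups, specific taxa in
#' exactly one, accessory taxa in more than one but not all. The three
#' sets partition the detected taxa. Per-group abundance shares use
#' group-mean relative abundances and sum to 100%.
#'
#' @param x abundance matrix (samples x taxa).
#' @param groups group label per sample (named by sample id or in row
#'   order).
#' @param min_samples detection threshold per group (default 1).
#' @return list with `core`, `accessory` (character vectors), `specific`
#'   (named list per group), `presence` (taxa x groups logical matrix),
#'   and `abundance_share` (data.frame per group: `core_pct`,
#'   `accessory_pct`, `specific_pct`).
#' @export
partition_taxa <- function(x, groups, min_samples = 1) {
  pres <- presence_by_group(x, groups, min_samples)
  if (!is.null(names(groups))) groups <- groups[rownames(x)]
  groups <- as.character(groups)
  if (any(table(groups) == 0)) stop("empty group")
  n_groups <- ncol(pres)
  npres <- rowSums(pres)
  detected <- rownames(pres)[npres > 0]
  core <- rownames(pres)[npres == n_groups]
  ## with a single group "core" and "present in exactly one group" would
  ## coincide; core takes precedence so the sets stay disjoint
  specific_all <- rownames(pres)[npres == 1 & npres < n_groups]
  accessory <- setdiff(detected, c(core, specific_all))
  specific <- lapply(colnames(pres), function(g) {
    intersect(specific_all, rownames(pres)[pres[, g]])
  })
  names(specific) <- colnames(pres)

  rel <- relative_abundance(x)
  share <- t(sapply(colnames(pres), function(g) {
    mu <- colMeans(rel[groups == g, , drop = FALSE])
    tot <- sum(mu)
    if (tot == 0) return(c(core_pct = 0, accessory_pct = 0, specific_pct = 0))
    c(core_pct = 100 * sum(mu[core]) / tot,
      accessory_pct = 100 * sum(mu[accessory]) / tot,
      specific_pct = 100 * sum(mu[specific_all]) / tot)
  }))
  list(core = core, accessory = accessory, specific = specific,
       presence = pres, abundance_share = as.data.frame(share))
}

#' UpSet-style intersection counts of group presence-sets
#'
#' For every non-empty subset S of groups, counts the taxa whose
#' presence-set equals S exactly; the counts over all subsets sum to the
#' number of detected taxa. Output is UpSet-compatible: one row per
#' observed subset with the member groups joined by `&`.
#'
#' @inheritParams partition_taxa
#' @return data.frame with columns `subset` (e.g. `"g1&g3"`), `degree`
#'   (subset size) and `count`, ordered by degree then count.
#' @export
intersection_counts <- function(x, groups, min_samples = 1) {
  pres <- presence_by_group(x, groups, min_samples)
  detected <- rowSums(pres) > 0
  pres <- pres[detected, , drop = FALSE]
  key <- apply(pres, 1, function(v) paste(colnames(pres)[v], collapse = "&"))
  tab <- table(key)
  out <- data.frame(subset = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$degree, -out$count, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
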