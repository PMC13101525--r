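#' Sample a lognormal metacommunity abundance distribution
#'
#' The regional species-abundance distribution from which local
#' communities are assembled. Lognormal with one shape parameter: larger
#' `shape` (the log-scale sigma) gives stronger dominance and lower
#' evenness. Abundances are normalised to sum to 1 and sorted descending.
#'
#' @param n_taxa number of taxa in the pool.
#' @param shape lognormal sigma (> 0); default 1.
#' @param seed integer seed.
#' @return named numeric vector `p` (taxon relative abundances, sum 1),
#'   names `taxon_001`, ... in descending-abundance order.
#' @export
sample_metacommunity <- function(n_taxa, shape = 1, seed = NULL) {
  if (n_taxa < 1) stop("n_taxa must be at least 1")
  if (shape <= 0) stop("shape must be positive")
  if (!is.null(seed)) set.seed(seed)
  w <- sort(stats::rlnorm(n_taxa, meanlog = 0, sdlog = shape),
            decreasing = TRUE)
  p <- w / sum(w)
  names(p) <- sprintf("taxon_%03d", seq_len(n_taxa))
  p
}

#' Simulate neutrally assembled local communities
#'
#' Runs a Moran-type per-individual replacement process — the discrete
#' process underlying the Sloan model's continuous approximation — for
#' each of `n_samples` independent local communities of fixed size `N`:
#' at each event one individual dies; with probability `m` it is replaced
#' by an immigrant drawn from the metacommunity, otherwise by a copy of
#' a uniformly chosen surviving local individual. Communities start as
#' multinomial(N, p) draws and are recorded after `burn_in` events
#' (default 50 N, sufficient for stationarity at the community sizes
#' used here). With `m = 1` every recorded sample is a fresh
#' multinomial(N, p) draw.
#'
#' @param meta metacommunity vector from [sample_metacommunity()] (named,
#'   positive, sums to 1).
#' @param N local community size (individuals).
#' @param m immigration probability per replacement, in (0, 1]; `m = 0`
#'   is disallowed (pure drift never reaches a stationary community).
#' @param n_samples number of local communities.
#' @param burn_in replacement events before recording; default `50 * N`.
#' @param seed integer seed.
#' @return count matrix (samples x taxa); every row sums to `N` exactly.
#' @export
simulate_local_communities <- function(meta, N, m, n_samples,
                                       burn_in = 50 * N, seed = NULL) {
  if (abs(sum(meta) - 1) > 1e-9 || any(meta <= 0))
    stop("meta must be a positive abundance vector summing to 1")
  if (N < 1) stop("N must be at least 1")
  if (m <= 0 || m > 1)
    stop("m must lie in (0, 1]; m = 0 gives pure drift with no stationary state")
  if (n_samples < 1) stop("n_samples must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- .moran_simulate(as.numeric(meta), as.integer(N), m,
                            as.integer(n_samples), as.numeric(burn_in))
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                           names(meta))
  counts
}

#' Aggregate a taxon table into a function table through a guild map
#'
#' A guild map assigns every taxon to exactly one functional guild and
#' every guild a weight profile over function ids. The function abundance
#' of a sample is the weighted sum of its taxon abundances:
#' `function_table = abundance %*% W` with `W[t, f]` the weight of
#' function f in the guild of taxon t. With binary unit weights this
#' collapses taxa into their guilds — the mechanism by which taxonomic
#' turnover leaves functional profiles unchanged.
#'
#' @param x abundance matrix (samples x taxa).
#' @param guilds a guild map from [make_guild_map()] (list with
#'   `guild_of`: named character vector taxon -> guild; `functions_of`:
#'   named list guild -> named numeric weight vector over function ids).
#' @return function abundance matrix (samples x functions).
#' @export
attach_functions <- function(x, guilds) {
  validate_abundance(x)
  unmapped <- setdiff(colnames(x), names(guilds$guild_of))
  if (length(unmapped) > 0)
    stop("taxa missing from the guild map: ", paste(unmapped, collapse = ", "))
  fun_ids <- sort(unique(unlist(lapply(guilds$functions_of, names))))
  W <- matrix(0, ncol(x), length(fun_ids),
              dimnames = list(colnames(x), fun_ids))
  for (t in colnames(x)) {
    wts <- guilds$functions_of[[guilds$guild_of[[t]]]]
    W[t, names(wts)] <- wts
  }
  x %*% W
}

#' Construct a guild map
#'
#' @param guild_of named character vector mapping taxon id to guild id.
#' @param functions_of named list mapping guild id to a named numeric
#'   weight vector over function ids; default: one unit-weight function
#'   per guild (`fn_<guild>`), the simplest structure that produces the
#'   taxonomy-function decoupling signal.
#' @return list with `guild_of` and `functions_of`, validated.
#' @export
make_guild_map <- function(guild_of, functions_of = NULL) {
  guild_of <- stats::setNames(as.character(guild_of), names(guild_of))
  guilds <- unique(guild_of)
  if (is.null(functions_of))
    functions_of <- stats::setNames(
      lapply(guilds, function(g) stats::setNames(1, paste0("fn_", g))),
      guilds)
  missing <- setdiff(guilds, names(functions_of))
  if (length(missing) > 0)
    stop("guilds without a function profile: ", paste(missing, collapse = ", "))
  if (any(vapply(functions_of, length, 1L) < 1))
    stop("every guild needs at least one function weight")
  list(guild_of = guild_of, functions_of = functions_of)
}

#' Generate a multi-strain dataset with functional redundancy
#'
#' Emulates host strains that deterministically select functional guilds
#' but stochastically select taxa within guilds (the "taxon lottery").
#' All strains share one guild-level target composition (lognormal over
#' guilds); within each guild, each strain draws its own taxon weights
#' from a sparse symmetric Dirichlet, so which of the guild's
#' `redundancy` interchangeable taxa dominates differs between strains.
#' Replicate samples are multinomial resamples of the strain composition
#' at a fixed depth, mimicking sequencing-depth sampling. With
#' `redundancy = 1` taxon- and guild-level composition coincide and all
#' decoupling signal vanishes.
#'
#' @param n_strains number of host strains (groups).
#' @param n_guilds number of functional guilds.
#' @param redundancy taxa per guild (>= 1).
#' @param samples_per_strain replicate samples per strain.
#' @param depth multinomial sampling depth per sample (default 10000).
#' @param guild_shape lognormal sigma of the guild target composition.
#' @param lottery_alpha Dirichlet concentration of the within-guild taxon
#'   lottery; values < 1 give sparse, strain-specific draws (default 0.5).
#' @param seed integer seed.
#' @return list of class `synthetic_dataset`: `abundance` (samples x
#'   taxa counts), `function_table` (samples x functions), `metadata`
#'   (data.frame `group`, `timepoint`, `replicate`), `guild_map`, and
#'   `truth` (all generator parameters).
#' @export
generate_redundant_strains <- function(n_strains, n_guilds, redundancy,
                                       samples_per_strain, depth = 10000,
                                       guild_shape = 1, lottery_alpha = 0.5,
                                       seed = NULL) {
  if (n_strains < 1 || n_guilds < 1 || samples_per_strain < 1)
    stop("counts must be at least 1")
  if (redundancy < 1) stop("redundancy must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  guild_ids <- sprintf("guild_%02d", seq_len(n_guilds))
  taxa <- as.vector(t(outer(guild_ids, seq_len(redundancy),
                            function(g, k) sprintf("%s_taxon_%02d", g, k))))
  guild_of <- stats::setNames(rep(guild_ids, each = redundancy), taxa)
  gm <- make_guild_map(guild_of)

  ## deterministic function filter: one target shared by every strain
  gw <- stats::rlnorm(n_guilds, 0, guild_shape)
  guild_target <- stats::setNames(gw / sum(gw), guild_ids)

  strains <- sprintf("strain_%02d", seq_len(n_strains))
  comp <- matrix(0, n_strains, length(taxa), dimnames = list(strains, taxa))
  for (s in seq_len(n_strains)) {
    for (g in seq_len(n_guilds)) {
      members <- taxa[guild_of[taxa] == guild_ids[g]]
      w <- stats::rgamma(redundancy, shape = lottery_alpha)
      if (sum(w) == 0) w[sample.int(redundancy, 1)] <- 1
      comp[s, members] <- guild_target[g] * w / sum(w)
    }
  }

  n_samples <- n_strains * samples_per_strain
  ab <- matrix(0, n_samples, length(taxa))
  ids <- character(n_samples)
  group <- character(n_samples); repl <- integer(n_samples)
  k <- 0
  for (s in seq_len(n_strains)) {
    for (r in seq_len(samples_per_strain)) {
      k <- k + 1
      ab[k, ] <- stats::rmultinom(1, depth, comp[s, ])[, 1]
      ids[k] <- sprintf("%s_rep_%02d", strains[s], r)
      group[k] <- strains[s]; repl[k] <- r
    }
  }
  dimnames(ab) <- list(ids, taxa)
  meta <- data.frame(group = group, timepoint = repl, replicate = repl,
                     row.names = ids, stringsAsFactors = FALSE)
  structure(list(abundance = ab,
                 function_table = attach_functions(ab, gm),
                 metadata = meta, guild_map = gm,
                 truth = list(n_strains = n_strains, n_guilds = n_guilds,
                              redundancy = redundancy,
                              samples_per_strain = samples_per_strain,
                              depth = depth, guild_shape = guild_shape,
                              lottery_alpha = lottery_alpha,
                              guild_target = guild_target,
                              strain_composition = comp, seed = seed)),
            class = "synthetic_dataset")
}

#' Generate a neutral-assembly dataset with known dispersal truth
#'
#' Convenience wrapper pairing [sample_metacommunity()] and
#' [simulate_local_communities()] and recording the ground-truth
#' parameters for recovery tests of [fit_ncm()].
#'
#' @inheritParams simulate_local_communities
#' @param n_taxa,shape metacommunity pool size and lognormal sigma.
#' @return list of class `synthetic_dataset` with `abundance`,
#'   `metadata` and `truth` (`m`, `N`, `Nm`, `meta`, `seed`).
#' @export
generate_neutral_dataset <- function(n_taxa = 500, shape = 1, N = 10000,
                                     m = 0.1, n_samples = 50,
                                     burn_in = 50 * N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meta <- sample_metacommunity(n_taxa, shape)
  ab <- simulate_local_communities(meta, N = N, m = m,
                                   n_samples = n_samples, burn_in = burn_in)
  md <- data.frame(group = "pooled", timepoint = 1L,
                   replicate = seq_len(n_samples),
                   row.names = rownames(ab), stringsAsFactors = FALSE)
  structure(list(abundance = ab, function_table = NULL, metadata = md,
                 guild_map = NULL,
                 truth = list(m = m, N = N, Nm = N * m, meta = meta,
                              burn_in = burn_in, seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic community dataset\n")
  cat(sprintf("  %d samples x %d taxa", nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$function_table))
    cat(sprintf("; %d functions", ncol(x$function_table)))
  cat("\n  groups:", paste(unique(x$metadata$group), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `abundance.tsv`, `functions.tsv` (if present), `metadata.tsv`
#' (samples as rows, first column the sample id) and `truth.json` with
#' the generator parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(dataset$abundance, file.path(dir, "abundance.tsv"))
  if (!is.null(dataset$function_table))
    write_abundance_table(dataset$function_table, file.path(dir, "functions.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  truth <- dataset$truth
  truth$strain_composition <- NULL   # large matrix; regenerable from seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
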