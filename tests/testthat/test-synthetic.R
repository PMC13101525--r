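test_that("metacommunity sampling normalises, sorts and respects the shape parameter", {
  expect_equal(unname(sample_metacommunity(1, shape = 2, seed = 1)), 1)

  p <- sample_metacommunity(100, shape = 1, seed = 7)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0))
  expect_true(all(diff(p) <= 0))
  expect_identical(p, sample_metacommunity(100, shape = 1, seed = 7))

  # larger lognormal sigma concentrates mass: lower Shannon evenness
  evenness <- function(q) -sum(q * log(q)) / log(length(q))
  p_wide <- sample_metacommunity(100, shape = 2, seed = 9)
  p_narrow <- sample_metacommunity(100, shape = 0.5, seed = 9)
  expect_lt(evenness(p_wide), evenness(p_narrow))

  expect_error(sample_metacommunity(0), "n_taxa")
  expect_error(sample_metacommunity(10, shape = 0), "shape")
})

test_that("every simulated community conserves exactly N individuals", {
  meta <- sample_metacommunity(40, seed = 1)
  for (m in c(0.05, 1)) {
    x <- simulate_local_communities(meta, N = 250, m = m, n_samples = 12,
                                    seed = 2)
    expect_true(all(rowSums(x) == 250))
    expect_identical(dim(x), c(12L, 40L))
  }
  expect_error(simulate_local_communities(meta, 100, m = 0, 5), "m = 0|m must")
})

test_that("m = 1 reproduces multinomial sampling from the metacommunity", {
  meta <- sample_metacommunity(20, shape = 1, seed = 3)
  N <- 100
  x <- simulate_local_communities(meta, N = N, m = 1, n_samples = 200,
                                  burn_in = N, seed = 4)
  rel_mean <- colMeans(x) / N
  se <- sqrt(meta * (1 - meta) / N / 200)
  expect_true(all(abs(rel_mean - meta) <= 3 * se + 1e-12))

  # chi-square goodness of fit of pooled counts against p, over 20 seeds
  pass <- vapply(1:20, function(s) {
    y <- simulate_local_communities(meta, N = 500, m = 1, n_samples = 10,
                                    burn_in = 500, seed = 100 + s)
    tot <- colSums(y)
    stat <- sum((tot - sum(tot) * meta)^2 / (sum(tot) * meta))
    pchisq(stat, df = length(meta) - 1, lower.tail = FALSE) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 19)
})

test_that("drift under low immigration erodes local richness", {
  meta <- sample_metacommunity(100, shape = 1, seed = 5)
  rich <- function(m, burn_in) {
    x <- simulate_local_communities(meta, N = 100, m = m, n_samples = 50,
                                    burn_in = burn_in, seed = 6)
    mean(rowSums(x > 0))
  }
  expect_lt(rich(0.001, 1e5), rich(1, 1e4))
})

test_that("identical seeds give bit-identical tables", {
  meta <- sample_metacommunity(30, seed = 8)
  a <- simulate_local_communities(meta, 200, 0.2, 8, seed = 99)
  b <- simulate_local_communities(meta, 200, 0.2, 8, seed = 99)
  expect_identical(a, b)

  d1 <- generate_redundant_strains(3, 5, 4, 3, seed = 12)
  d2 <- generate_redundant_strains(3, 5, 4, 3, seed = 12)
  expect_identical(d1$abundance, d2$abundance)
  expect_identical(d1$function_table, d2$function_table)
})

test_that("attach_functions is the guild-weighted linear map", {
  x <- random_table(4, 6, 2)
  # identity map: each taxon its own guild with one unit-weight function
  gm_id <- make_guild_map(setNames(colnames(x), colnames(x)))
  fx <- attach_functions(x, gm_id)
  expect_identical(colnames(fx), paste0("fn_", colnames(x)))
  expect_equal(unname(fx), unname(x))

  # two taxa in one guild: swapping their abundances leaves functions fixed
  gmap <- setNames(c("g1", "g1", "g2", "g2", "g3", "g3"), colnames(x))
  gm <- make_guild_map(gmap)
  fx1 <- attach_functions(x, gm)
  xs <- x
  xs[, c("t1", "t2")] <- x[, c("t2", "t1")]
  expect_equal(attach_functions(xs, gm), fx1)

  # general weights agree with the direct matrix-product oracle
  fns <- list(g1 = c(f1 = 1, f2 = 0.5), g2 = c(f2 = 2), g3 = c(f3 = 1))
  gm2 <- make_guild_map(gmap, fns)
  fx2 <- attach_functions(x, gm2)
  W <- matrix(0, 6, 3, dimnames = list(colnames(x), c("f1", "f2", "f3")))
  for (t in colnames(x)) {
    w <- fns[[gmap[[t]]]]
    W[t, names(w)] <- w
  }
  expect_equal(fx2, x %*% W)

  expect_error(attach_functions(x, make_guild_map(gmap[-1])), "t1")
})

test_that("redundancy = 1 collapses the taxon/function distinction", {
  ds <- generate_redundant_strains(4, 12, 1, 4, seed = 13)
  bc_t <- beta_diversity(ds$abundance, "bray_curtis")
  bc_f <- beta_diversity(ds$function_table, "bray_curtis")
  expect_equal(bc_t, bc_f, tolerance = 1e-12)
})

test_that("redundant guilds decouple function from taxonomy across strains", {
  g <- function(ds) setNames(ds$metadata$group, rownames(ds$metadata))
  between_mean <- function(d, grp) {
    lt <- lower.tri(d)
    mean(d[lt][outer(grp, grp, "!=")[lt]])
  }
  ds8 <- generate_redundant_strains(6, 20, 8, 6, seed = 14)
  bt <- between_mean(beta_diversity(ds8$abundance), g(ds8))
  bf <- between_mean(beta_diversity(ds8$function_table), g(ds8))
  expect_lt(bf, bt)

  # function-side separation stays at sampling-noise level as redundancy
  # grows, while the taxon side increases
  vals <- lapply(c(1, 2, 8), function(r) {
    ds <- generate_redundant_strains(6, 20, r, 6, seed = 15)
    list(f = between_mean(beta_diversity(ds$function_table), g(ds)),
         t = between_mean(beta_diversity(ds$abundance), g(ds)))
  })
  f_means <- vapply(vals, `[[`, numeric(1), "f")
  t_means <- vapply(vals, `[[`, numeric(1), "t")
  expect_true(all(diff(f_means) <= 0.01))   # non-increasing up to noise
  expect_true(all(diff(t_means) > 0))
})

test_that("a single strain makes every detected taxon core", {
  ds <- generate_redundant_strains(1, 8, 3, 5, seed = 16)
  part <- partition_taxa(ds$abundance,
                         setNames(ds$metadata$group, rownames(ds$metadata)))
  detected <- colnames(ds$abundance)[colSums(ds$abundance > 0) > 0]
  expect_setequal(part$core, detected)
  expect_length(part$accessory, 0)
  expect_equal(sum(lengths(part$specific)), 0)
})

test_that("synthetic datasets serialise to TSV + JSON and read back", {
  ds <- generate_redundant_strains(3, 6, 2, 3, seed = 17)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  x <- read_abundance_table(file.path(dir, "abundance.tsv"))
  expect_equal(x, ds$abundance)
  fx <- read_abundance_table(file.path(dir, "functions.tsv"))
  expect_equal(fx, ds$function_table)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$group, ds$metadata$group)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$redundancy, 2)
  expect_equal(truth$seed, 17)
})
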