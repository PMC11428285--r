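test_that("planted well-separated micelles are recovered exactly", {
  g <- gen_planted_micelles(3, c("3A2BC" = 20), box = c(20, 20, 20), seed = 42)
  mset <- find_micelles(g$state)
  expect_equal(length(mset$clusters), 3)
  expect_equal(mset$n_chains, rep(20L, 3))
  expect_identical(canonical_clusters(mset$clusters),
                   canonical_clusters(g$truth$clusters))
  expect_equal(length(mset$free_chains), 0)
})

test_that("groups of three or fewer chains count as free surfactant", {
  g <- gen_planted_micelles(1, c("3A2BC" = 3), box = c(15, 15, 15), seed = 7)
  mset <- find_micelles(g$state)
  expect_equal(length(mset$clusters), 0)
  expect_equal(sort(mset$free_chains), sort(g$truth$clusters[[1]]))
  # two isolated chains: no clusters either
  g2 <- gen_planted_micelles(0, c("3A2BC" = 1), box = c(15, 15, 15),
                             n_free_chains = 2, seed = 8)
  mset2 <- find_micelles(g2$state)
  expect_equal(length(mset2$clusters), 0)
  expect_equal(mset2$total_chains, 2)
})

test_that("cluster finder agrees with brute-force connected components", {
  # dense random configurations where clusters are ambiguous by eye
  for (seed in 1:4) {
    set.seed(seed)
    nch <- 60
    tm <- build_molecule_templates("3A2BC")[[1]]
    pos <- NULL; mol <- NULL; species <- NULL; bonds <- NULL
    at <- 0
    for (m in seq_len(nch)) {
      start <- runif(3) * 8
      p <- matrix(start, 6, 3, byrow = TRUE) +
        apply(matrix(rnorm(18, sd = 0.3), 6, 3), 2, cumsum)
      pos <- rbind(pos, p)
      mol <- c(mol, rep(m, 6))
      species <- c(species, tm$beads)
      bonds <- rbind(bonds, tm$bonds + at)
      at <- at + 6
    }
    st <- dpd_state(pos, species, c(8, 8, 8), molecule_id = mol,
                    molecule_name = rep("3A2BC", length(mol)), bonds = bonds)
    mset <- find_micelles(st, cutoff = 0.8)
    oracle <- brute_force_clusters(st, cutoff = 0.8)
    expect_identical(canonical_clusters(mset$clusters),
                     canonical_clusters(oracle))
    # chain bookkeeping closes: clustered + free = all chains
    expect_equal(sum(mset$n_chains) + length(mset$free_chains),
                 mset$total_chains)
  }
})

test_that("clustering is invariant under chain relabeling and rigid translation", {
  g <- gen_planted_micelles(2, c("3A2BC" = 10), box = c(16, 16, 16), seed = 3)
  st <- g$state
  m0 <- find_micelles(st)
  # rigid translation (with periodic wrap)
  st2 <- st
  st2$positions <- sweep(st2$positions, 2, c(3.3, -2.1, 7.9), "+")
  st2 <- dpdiss:::wrap_state(st2)
  m2 <- find_micelles(st2)
  expect_identical(canonical_clusters(m0$clusters),
                   canonical_clusters(m2$clusters))
  # relabeling: reverse bead order wholesale
  n <- nrow(st$positions)
  rev_idx <- n:1
  map <- integer(n); map[rev_idx] <- seq_len(n)
  st3 <- dpd_state(st$positions[rev_idx, ], st$species[rev_idx], st$box,
                   molecule_id = max(st$molecule_id) + 1 -
                     st$molecule_id[rev_idx],
                   molecule_name = st$molecule_name[rev_idx],
                   bonds = matrix(map[st$bonds], ncol = 2))
  m3 <- find_micelles(st3)
  expect_equal(sort(m3$n_chains), sort(m0$n_chains))
})

test_that("micelle statistics reproduce the size-metric arithmetic", {
  # pure-surfactant identity: V = 6 * mean chains, metric = V^(-1/3)
  expect_equal(round(aggregate_size_metric(35.0), 3), 0.168)
  expect_equal(round(aggregate_size_metric(159.3), 3), 0.102)
  # hypothetical single cluster of 8 single-bead chains: V = 8, metric 0.5
  expect_equal(aggregate_size_metric(8, beads_per_chain = 1), 0.5)
  # oil-loaded micelles at the 10:70 oil:surfactant bead ratio
  expect_equal(round(aggregate_size_metric(75.9, oil_bead_ratio = 10 / 70), 3),
               0.124)
  # statistics from a found micelle set agree with the identity
  g <- gen_planted_micelles(3, c("3A2BC" = 20), box = c(20, 20, 20), seed = 2)
  ms <- micelle_statistics(find_micelles(g$state))
  expect_equal(ms$mean_chains, 20)
  expect_equal(ms$mean_volume, 120)
  expect_equal(ms$size_metric, aggregate_size_metric(20))
})

test_that("empty micelle sets give a flagged all-zero summary", {
  g <- gen_planted_micelles(0, c("3A2BC" = 1), box = c(12, 12, 12),
                            n_free_chains = 5, seed = 1)
  ms <- micelle_statistics(find_micelles(g$state))
  expect_true(ms$empty)
  expect_equal(ms$n_micelles, 0)
  expect_equal(ms$size_metric, 0)
})

test_that("oil molecules attach to their host micelle and count in its volume", {
  g <- gen_planted_micelles(2, c("3A2BC" = 8), box = c(18, 18, 18),
                            oil_per_cluster = 3, oil_template = "oil2",
                            seed = 11)
  mset <- find_micelles(g$state)
  expect_equal(length(mset$clusters), 2)
  expect_equal(mset$oil_beads, c(6L, 6L))  # 3 oil2 molecules = 6 beads each
  ms <- micelle_statistics(mset)
  expect_equal(ms$mean_volume, 8 * 6 + 6)
})

test_that("per-micelle composition and mixing index behave at the extremes", {
  # evenly mixed: every fraction 1/2, mixing index 0
  g <- gen_planted_micelles(3, c("3A2BC" = 10, "4ABC" = 10),
                            box = c(20, 20, 20), seed = 5)
  comp <- micelle_composition(find_micelles(g$state))
  expect_equal(unname(comp[["3A2BC"]]), rep(0.5, 3))
  expect_equal(attr(comp, "mixing_index"), 0)
  # fully demixed two-point distribution at f = 1/2: index sqrt(f(1-f)) = 0.5
  g1 <- gen_planted_micelles(1, c("3A2BC" = 10), box = c(20, 20, 20), seed = 6)
  g2 <- gen_planted_micelles(1, c("4ABC" = 10), box = c(20, 20, 20), seed = 7)
  st <- g1$state
  off <- nrow(st$positions)
  moloff <- max(st$molecule_id)
  st2 <- g2$state
  st2$positions[, 1] <- (st2$positions[, 1] + 10) %% 20
  merged <- dpd_state(rbind(st$positions, st2$positions),
                      c(st$species, st2$species), st$box,
                      molecule_id = c(st$molecule_id,
                                      st2$molecule_id + moloff),
                      molecule_name = c(st$molecule_name, st2$molecule_name),
                      bonds = rbind(st$bonds, st2$bonds + off))
  compd <- micelle_composition(find_micelles(merged))
  expect_equal(attr(compd, "mixing_index"), 0.5, tolerance = 1e-12)
  # pure system: degenerate fractions {1}
  compp <- micelle_composition(find_micelles(g1$state))
  expect_equal(unname(compp[["3A2BC"]]), 1)
})

test_that("random mixed assignment lands near the global fraction", {
  # clusters drawn at global fraction f: per-cluster fractions within
  # binomial sampling error
  f <- 0.7; n_per <- 40
  set.seed(99)
  g <- gen_planted_micelles(4, c("3A2BC" = n_per), box = c(26, 26, 26),
                            seed = 13)
  st <- g$state
  # relabel a random subset of chains as 4ABC (same A-bead count not needed
  # for composition bookkeeping)
  chains <- unique(st$molecule_id)
  flip <- sample(chains, round((1 - f) * length(chains)))
  st$molecule_name[st$molecule_id %in% flip] <- "4ABC"
  comp <- micelle_composition(find_micelles(st))
  sem <- sqrt(f * (1 - f) / n_per)
  expect_true(all(abs(comp[["3A2BC"]] - f) < 4 * sem))
})
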