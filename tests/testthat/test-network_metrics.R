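complete_adj <- function(n) matrix(1L, n, n) - diag(n)

inward_star <- function(n) {
  A <- matrix(0L, n, n)
  A[2:n, 1] <- 1L
  A
}

test_that("density matches hand enumeration and endpoints", {
  expect_equal(net_density(complete_adj(5)), 1)
  expect_equal(net_density(matrix(0L, 5, 5)), 0)
  A <- matrix(0L, 4, 4)
  A[cbind(c(1, 1, 2, 3, 4, 4), c(2, 3, 1, 4, 1, 2))] <- 1L
  expect_equal(net_density(A), 6 / 12)  # 12 ordered pairs enumerated by hand
  expect_error(net_density(matrix(0L, 1, 1)), "n < 2")
})

test_that("centralization is 1 for an inward star, 0 for regular networks", {
  expect_equal(degree_centralization(inward_star(6)), 1)
  expect_equal(degree_centralization(complete_adj(6)), 0)
  # 5 nodes with in-degrees (4,2,1,1,0): direct formula evaluation
  A <- matrix(0L, 5, 5)
  A[2:5, 1] <- 1L                       # node 1 receives from all
  A[cbind(c(1, 3, 1, 5), c(2, 2, 3, 4))] <- 1L
  din <- colSums(A)
  expect_equal(din, c(4, 2, 1, 1, 0), ignore_attr = TRUE)
  expect_equal(degree_centralization(A), sum(max(din) - din) / 16)
  expect_equal(degree_centralization(A), bf_centralization_in(A))
  expect_error(degree_centralization(matrix(0L, 2, 2)), "n < 3")
})

test_that("clustering matches the neighbour-pair definition", {
  expect_equal(clustering_coef(complete_adj(5)), 1)
  expect_equal(clustering_coef(inward_star(6)), 0)
  # triangle 1-2-3 plus pendant 4 attached to 3:
  # locals 1, 1, 1/3, 0 -> mean 7/12
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 1] <- 1L
  A[4, 3] <- 1L
  expect_equal(clustering_coef(A), 7 / 12)
  expect_equal(clustering_coef(A), bf_clustering(A))
})

test_that("reciprocity counts mutual ties", {
  M <- matrix(0L, 4, 4); M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- 1L
  expect_equal(reciprocity(M), 1)
  Tn <- matrix(0L, 4, 4); Tn[upper.tri(Tn)] <- 1L  # acyclic tournament
  expect_equal(reciprocity(Tn), 0)
  # 3 mutual pairs + 2 one-way edges = 8 directed edges, 6 reciprocated
  A <- matrix(0L, 5, 5)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- A[4, 5] <- A[5, 4] <- 1L
  A[1, 3] <- A[4, 1] <- 1L
  expect_equal(reciprocity(A), 6 / 8)
  expect_error(reciprocity(matrix(0L, 3, 3)), "zero ties")
})

test_that("composition is a distribution over the nine types", {
  p <- composition(rep("social_services", 10))
  expect_equal(p[["social_services"]], 1)
  expect_equal(sum(p), 1)
  p4 <- composition(c("primary_care", "crisis_outreach", "nursing_home",
                      "other"))
  expect_equal(unname(p4[c("primary_care", "crisis_outreach",
                           "nursing_home", "other")]), rep(0.25, 4))
  counts <- c(13, 11, 10, 12, 21, 17, 10, 3, 3)
  types <- rep(carenets_vocab()$service_types, counts)
  expect_equal(unname(composition(types)), counts / 100)
})

test_that("dissimilarity index is half the L1 distance", {
  ref <- c(0.5, 0.5, rep(0, 7))
  expect_equal(dissimilarity_index(ref, ref), 0)
  expect_equal(dissimilarity_index(c(1, rep(0, 8)), ref), 0.5)
  a <- c(0.1, 0.2, 0.05, 0.05, 0.3, 0.1, 0.1, 0.05, 0.05)
  b <- c(0.2, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1, 0.05, 0.05)
  expect_equal(dissimilarity_index(a, b), sum(abs(a - b)) / 2)
  expect_error(dissimilarity_index(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("Coleman index hits its endpoints and missing cases", {
  types <- c("primary_care", "primary_care", "other", "other", "other")
  A <- matrix(0L, 5, 5); A[1, 2] <- A[2, 1] <- 1L
  nw <- new_network(A, types)
  expect_equal(coleman_index(nw, "primary_care"), 1)

  A2 <- matrix(0L, 5, 5); A2[1, 3] <- A2[2, 4] <- 1L
  expect_equal(coleman_index(new_network(A2, types), "primary_care"), -1)

  # no out-ties from the group: missing, not zero
  A3 <- matrix(0L, 5, 5); A3[3, 1] <- 1L
  expect_true(is.na(coleman_index(new_network(A3, types), "primary_care")))
  # group is the whole network: expectation degenerate
  expect_true(is.na(coleman_index(new_network(A, "primary_care"),
                                  "primary_care")))
  # merged groups
  types_m <- c("social_services", "rehabilitation", "other", "other", "other")
  nw_m <- new_network(A, types_m)
  expect_equal(coleman_index(nw_m, c("social_services", "rehabilitation")), 1)
})

test_that("Coleman index centres on zero under random mixing", {
  # balanced group (e = 0.5) so the asymmetric normalization is symmetric
  set.seed(42)
  types <- rep(c("primary_care", "other"), c(11, 10))
  vals <- replicate(400, coleman_index(new_network(random_adjacency(21, 0.3),
                                                   types), "primary_care"))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("metrics agree with brute-force enumeration on random graphs", {
  set.seed(7)
  types5 <- c("primary_care", "primary_care", "other", "other", "other")
  for (r in 1:150) {
    n <- sample(3:5, 1)
    A <- random_adjacency(n, stats::runif(1, 0.2, 0.8))
    expect_equal(net_density(A), bf_density(A))
    expect_equal(degree_centralization(A), bf_centralization_in(A))
    expect_equal(clustering_coef(A), bf_clustering(A))
    if (sum(A) > 0) expect_equal(reciprocity(A), bf_reciprocity(A))
    if (n == 5) {
      nw <- new_network(A, types5)
      expect_equal(coleman_index(nw, "primary_care"),
                   bf_coleman(A, types5, "primary_care"))
    }
  }
})

test_that("density and reciprocity agree with igraph", {
  set.seed(8)
  for (r in 1:25) {
    A <- random_adjacency(sample(4:30, 1), stats::runif(1, 0.1, 0.7))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    expect_equal(net_density(A), igraph::edge_density(g))
    if (sum(A) > 0)
      expect_equal(reciprocity(A), igraph::reciprocity(g))
  }
})

test_that("metrics stay in range and are label-invariant", {
  set.seed(9)
  for (r in 1:300) {
    n <- sample(3:60, 1)
    A <- random_adjacency(n, stats::runif(1, 0.05, 0.95))
    types <- sample(carenets_vocab()$service_types, n, replace = TRUE)
    nw <- new_network(A, types)
    d <- net_density(A); cz <- degree_centralization(A)
    cl <- clustering_coef(A)
    expect_true(d >= 0 && d <= 1)
    expect_true(cz >= 0 && cz <= 1)
    expect_true(cl >= 0 && cl <= 1)
    if (sum(A) > 0) {
      rc <- reciprocity(A)
      expect_true(rc >= 0 && rc <= 1)
    }
    co <- coleman_index(nw, types[1])
    expect_true(is.na(co) || (co >= -1 && co <= 1))
    expect_equal(sum(composition(nw)), 1)

    if (r <= 60) {  # label invariance
      perm <- sample(n)
      nw_p <- new_network(A[perm, perm], types[perm])
      expect_equal(net_density(nw_p$adjacency), d)
      expect_equal(degree_centralization(nw_p$adjacency), cz)
      expect_equal(clustering_coef(nw_p$adjacency), cl)
      expect_equal(coleman_index(nw_p, types[1]), co)
    }
  }
})

test_that("metrics_table summarizes per-network rows consistently", {
  nw1 <- new_network(complete_adj(5), "other")
  single <- metrics_table(list(nw1))
  s <- single$summary
  expect_equal(s$mean[s$metric == "density"], 1)
  expect_equal(s$std[s$metric == "density"], 0)
  expect_equal(s$min[s$metric == "density"],
               s$max[s$metric == "density"])

  # densities 0.4 and 0.6 -> mean 0.5
  set.seed(10)
  mk <- function(target) {
    n <- 10
    A <- matrix(0L, n, n)
    ord <- which(upper.tri(A) | lower.tri(A))
    A[sample(ord, round(target * n * (n - 1)))] <- 1L
    new_network(A, "other")
  }
  two <- metrics_table(list(mk(0.4), mk(0.6)))
  expect_equal(two$summary$mean[two$summary$metric == "density"], 0.5)

  study <- generate_study(sim_config(size_range = c(10, 30), n_clusters = 2,
                                     cluster_size = 2), seed = 3)
  mt <- study$metrics
  for (m in c("density", "centralization", "clustering", "n_services")) {
    v <- mt$metrics[[m]]
    expect_equal(mt$summary$mean[mt$summary$metric == m], mean(v))
    expect_equal(mt$summary$std[mt$summary$metric == m], sd(v))
    expect_equal(mt$summary$min[mt$summary$metric == m], min(v))
    expect_equal(mt$summary$max[mt$summary$metric == m], max(v))
  }
  # composition reference: unweighted mean across networks
  comps <- sapply(study$networks, composition)
  expect_equal(mt$reference, rowMeans(comps))
})

test_that("correlation matrix matches the Pearson formula and flags constants", {
  set.seed(11)
  df <- data.frame(network_id = sprintf("n%02d", 1:19),
                   n_services = rpois(19, 50))
  df$density <- 0.3 + 0.2 * scale(df$n_services)[, 1] + rnorm(19, 0, 0.05)
  df$twin <- df$density
  df$anti <- -df$density
  df$flat <- 1

  expect_warning(cm <- correlation_matrix(df, c("density", "twin", "anti",
                                                "n_services", "flat")),
                 "constant")
  expect_equal(cm$r["density", "twin"], 1)
  expect_equal(cm$r["density", "anti"], -1)
  expect_true(is.na(cm$r["density", "flat"]))
  expect_equal(cm$r["density", "n_services"],
               bf_pearson(df$density, df$n_services), tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 5))
  pt <- cor.test(df$density, df$n_services)
  expect_equal(cm$p["density", "n_services"], pt$p.value)
})
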