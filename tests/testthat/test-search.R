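path_graph <- function(ids = c("a", "b", "c", "d")) {
  make_network(data.frame(from = ids[-length(ids)], to = ids[-1]))
}

fake_seed_list <- function(nodes) {
  data.frame(node = nodes, score = seq_along(nodes) - 10,
             max_corr = rev(seq_along(nodes)) / 10,
             stringsAsFactors = FALSE)
}

test_that("seed_network keeps the largest connected component with tie rules", {
  target <- make_network(data.frame(from = c("a", "c"), to = c("b", "d")),
                         nodes = c("a", "b", "c", "d", "e"))
  sh <- seed_network(target, fake_seed_list(c("a", "b", "e")))
  expect_setequal(sh$members, c("a", "b"))

  # all seeds isolated: single best-ranked seed
  sh2 <- seed_network(target, fake_seed_list(c("e", "a")))
  expect_equal(sh2$members, "e")

  # two equal components: the one holding the top-ranked seed wins
  sh3 <- seed_network(target, fake_seed_list(c("c", "d", "a", "b")))
  expect_setequal(sh3$members, c("c", "d"))
  expect_error(seed_network(target, fake_seed_list(character())), "empty")
})

test_that("conductance matches hand-computed path-graph values", {
  pg <- path_graph()
  expect_equal(conductance(pg, c("a", "b")), 1.0)
  expect_equal(conductance(pg, c("a", "b"), mode = "standard"), 1 / 3)
  expect_equal(conductance(pg, net_nodes(pg)), 0)
  expect_equal(conductance(pg, "b"), Inf)  # no internal edge
  expect_error(conductance(pg, character()), "non-empty")
  expect_error(conductance(pg, "nope"), "belong")
})

test_that("both conductance modes equal the brute-force edge count oracle", {
  withr::local_seed(23)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    net <- make_network(rand_connected_edges(n, runif(1, 0.15, 0.5)))
    members <- sample(net_nodes(net), sample(1:(n - 1), 1))
    for (mode in c("module", "standard")) {
      expect_equal(conductance(net, members, mode),
                   oracle_conductance(net, members, mode))
    }
    phi_std <- conductance(net, members, mode = "standard")
    if (is.finite(phi_std)) expect_true(phi_std >= 0 && phi_std <= 1)
  }
})

test_that("extension accepts the hand-worked path-graph step and rewards neighbors", {
  pg <- path_graph()
  sh <- subnetwork(pg, c("a", "b"))
  ext <- extend(pg, sh, query_size = 4)
  # adding c: cut 1, internal 2 -> phi 0.5 <= 0.95 * 1.0; then d: 0/3 = 0
  expect_equal(ext$trace, c(1.0, 0.5, 0))
  expect_setequal(ext$subnetwork$members, c("a", "b", "c", "d"))
  expect_equal(ext$rewards[["b"]], 1L)  # adjacent to newly added c
  expect_equal(ext$rewards[["a"]], 0L)
  expect_equal(ext$rewards[["c"]], 1L)  # later gains d
  expect_equal(ext$rewards[["d"]], 0L)
})

test_that("extension respects the size cap and the no-candidate stop", {
  pg <- path_graph()
  full <- subnetwork(pg, net_nodes(pg))
  ext <- extend(pg, full, query_size = 4)
  expect_equal(ext$subnetwork$members, full$members)
  expect_equal(ext$trace, conductance(pg, full))

  two <- subnetwork(pg, c("a", "b"))
  capped <- extend(pg, two, query_size = 1, cap_factor = 2)
  expect_equal(length(capped$subnetwork$members), 2L)
})

test_that("greedy steps are optimal, capped, and honor the reduction rule", {
  withr::local_seed(77)
  for (rep in 1:10) {
    n <- sample(12:30, 1)
    net <- make_network(rand_connected_edges(n, runif(1, 0.15, 0.3)))
    qsize <- sample(3:8, 1)
    seeds <- sample(net_nodes(net), sample(2:qsize, 1))
    sh <- subnetwork(net, seeds)
    ext <- extend(net, sh, query_size = qsize)
    expect_lte(length(ext$subnetwork$members), 2 * qsize)
    # replay: each accepted node must be the step-minimal candidate and
    # reduce conductance by at least 5% (or any finite value from Inf)
    members <- sh$members
    phi <- oracle_conductance(net, members)
    for (i in seq_len(nrow(ext$steps))) {
      cand <- setdiff(unique(unlist(
        igraph::adjacent_vertices(net, members) |> lapply(names))), members)
      phis <- vapply(cand, function(u)
        oracle_conductance(net, c(members, u)), 0)
      chosen <- ext$steps$node[i]
      expect_equal(ext$steps$conductance[i], min(phis))
      expect_equal(oracle_conductance(net, c(members, chosen)), min(phis))
      if (is.finite(phi)) {
        expect_lte(ext$steps$conductance[i], (1 - 0.05) * phi)
      } else {
        expect_true(is.finite(ext$steps$conductance[i]))
      }
      members <- c(members, chosen)
      phi <- ext$steps$conductance[i]
    }
    # trace decreases by >= 5% per step after any Inf start
    tr <- ext$trace
    fin <- which(is.finite(tr))
    if (length(fin) > 1) {
      expect_true(all(tr[fin][-1] <= (1 - 0.05) * tr[fin][-length(fin)] + 1e-12))
    }
  }
})

test_that("pruning keeps seeds and strictly-above-threshold rewards only", {
  pg <- path_graph()
  H <- subnetwork(pg, c("a", "b", "c"))
  pruned <- prune(H, c(a = 0L, b = 0L, c = 1L), seeds = "a", threshold = 0L)
  expect_setequal(pruned$members, c("a", "c"))

  all_seeds <- prune(H, c(a = 0L, b = 0L, c = 0L), seeds = H$members)
  expect_equal(all_seeds$members, H$members)

  strict <- prune(subnetwork(pg, c("b", "c")), c(b = 1L, c = 2L),
                  seeds = character(), threshold = 1L)
  expect_equal(strict$members, "c")
})

test_that("run_query recovers an implanted copy and degenerate queries work", {
  gp <- generate_pair(synth_config(query_size = 7, background_size = 80,
                                   rng_seed = 5))
  res <- run_query(gp$query, gp$target, gp$sim)
  expect_setequal(res$final, gp$truth$implanted_nodes)
  expect_equal(recovery_score(res, gp$truth), 1.0)
  expect_true(all(res$seeds %in% res$final))

  # single-node query with one perfect match
  q1 <- make_network(nodes = "q")
  t1 <- make_network(data.frame(from = c("x", "y"), to = c("y", "z")))
  s1 <- similarity_table("q", "x", 75)
  r1 <- run_query(q1, t1, s1)
  expect_equal(r1$final, "x")

  # no homologs at all
  expect_error(run_query(q1, t1, similarity_table("q", "none", 5)),
               "empty")
})

test_that("run_query is deterministic", {
  gp <- generate_pair(synth_config(query_size = 6, background_size = 60,
                                   p_node_insert = 0.2, p_edge_rewire = 0.1,
                                   spurious_pair_rate = 0.03, rng_seed = 8))
  r1 <- run_query(gp$query, gp$target, gp$sim)
  r2 <- run_query(gp$query, gp$target, gp$sim)
  expect_identical(r1, r2)
})
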