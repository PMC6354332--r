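three_channel_example <- function() {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- 0.1
  m["A", "C"] <- m["C", "A"] <- 0.2
  m["B", "C"] <- m["C", "B"] <- 0.6
  m
}

test_that("the mean-threshold rule keeps strictly supra-mean pairs", {
  net <- threshold_network(three_channel_example())
  expect_equal(net$threshold, 0.3)
  expect_equal(igraph::ecount(net$graph), 1)
  e <- igraph::as_edgelist(net$graph)
  expect_setequal(as.character(e), c("B", "C"))

  flat <- matrix(0.4, 3, 3); diag(flat) <- 0
  expect_equal(igraph::ecount(threshold_network(flat)$graph), 0)  # strict >

  full <- threshold_network(three_channel_example(), rule = "fixed",
                            value = -Inf)
  expect_equal(igraph::ecount(full$graph), 3 * 2 / 2)
})

test_that("raising the threshold never adds an edge (nested edge sets)", {
  set.seed(71)
  m <- matrix(0, 10, 10)
  m[upper.tri(m)] <- runif(45)
  m <- m + t(m)
  edges_at <- lapply(c(0.2, 0.4, 0.6, 0.8), function(v) {
    g <- threshold_network(m, rule = "fixed", value = v)$graph
    apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
  })
  for (k in 1:3)
    expect_true(all(edges_at[[k + 1]] %in% edges_at[[k]]))
})

test_that("every produced network satisfies the handshake lemma", {
  set.seed(72)
  for (i in 1:10) {
    m <- matrix(0, 8, 8)
    m[upper.tri(m)] <- runif(28)
    m <- m + t(m)
    g <- threshold_network(m)$graph
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  }
})

test_that("top-k edges rank by value with lexicographic tie-breaks", {
  m <- three_channel_example()
  expect_equal(top_k_edges(m, 1)$value, 0.6)
  expect_equal(nrow(top_k_edges(m, 99)), 3)          # saturates at all pairs

  tied <- matrix(0, 4, 4,
                 dimnames = list(c("D", "B", "C", "A"),
                                 c("D", "B", "C", "A")))
  tied["D", "B"] <- tied["B", "D"] <- 0.5
  tied["C", "A"] <- tied["A", "C"] <- 0.5
  tied["D", "C"] <- tied["C", "D"] <- 0.9
  top2 <- top_k_edges(tied, 2)
  expect_equal(top2$value, c(0.9, 0.5))
  expect_equal(unname(unlist(top2[2, 1:2])), c("A", "C"))  # {A,C} < {B,D}
})

test_that("core nodes are the maximum-degree set, sorted", {
  labs <- c("Pz", "F3", "F4", "T5", "O1")
  star <- make_star_network("Pz", c("F3", "F4", "T5", "O1"), labs)
  expect_identical(core_nodes(star), "Pz")

  ring <- matrix(0, 4, 4, dimnames = list(labs[1:4], labs[1:4]))
  for (i in 1:4) { j <- i %% 4 + 1; ring[i, j] <- ring[j, i] <- 1 }
  cyc <- threshold_network(ring, rule = "fixed", value = 0.5)
  expect_identical(core_nodes(cyc), sort(labs[1:4]))  # complete tie

  none <- threshold_network(ring, rule = "fixed", value = 2)
  expect_length(core_nodes(none), 0)
  expect_true(attr(core_nodes(none), "empty"))
})

test_that("degree dynamics track windows and reject node mismatches", {
  labs <- c("A", "B", "C")
  n1 <- make_star_network("A", c("B", "C"), labs)
  dd <- degree_dynamics(list(n1, n1, n1))
  expect_equal(dd$mean_degree, rep(4 / 3, 3))
  expect_equal(rowSums(dd$degrees),
               vapply(list(n1, n1, n1),
                      function(n) 2 * igraph::ecount(n$graph), 0))
  n2 <- make_star_network("X", c("Y", "Z"), c("X", "Y", "Z"))
  expect_error(degree_dynamics(list(n1, n2)), "node sets")
})

test_that("the main path collapses duplicates into the field notation", {
  labs <- c("Pz", "F3", "F4", "T5", "O1")
  w1 <- make_star_network("Pz", c("F3", "O1"), labs)
  w2 <- make_star_network(c("F3", "F4"), c("Pz", "O1", "T5"), labs)
  w3 <- make_star_network(c("F3", "F4"), c("Pz", "O1", "T5"), labs)
  w4 <- make_star_network("T5", c("Pz", "F3", "O1"), labs)
  path <- main_path(list(w1, w2, w3, w4))
  expect_identical(path$rendered, "Pz-(F3\\F4)-T5")

  single <- main_path(list(w1))
  expect_identical(single$rendered, "Pz")
  empty <- threshold_network(matrix(0, 3, 3), rule = "fixed", value = 1)
  expect_error(main_path(list(empty, empty)), "edgeless")
})

test_that("consensus foci count core appearances across feature networks", {
  labs <- c("T3", "T5", "O1", "F7")
  starT3 <- make_star_network("T3", c("T5", "O1", "F7"), labs)
  starT5 <- make_star_network("T5", c("T3", "O1", "F7"), labs)
  starO1 <- make_star_network("O1", c("T3", "T5"), labs)
  nets <- list(CD = list(starT3), ApEn = list(starT3),
               HE = list(starT3), PCAI = list(starT3))
  expect_identical(consensus_foci(nets)[1], "T3")     # unanimity

  nets2 <- list(CD = list(starT3, starT5), ApEn = list(starT3, starT5),
                HE = list(starT3, starT5), PCAI = list(starT3, starO1))
  cf <- consensus_foci(nets2, top = 2)
  expect_identical(as.character(cf), c("T3", "T5"))   # counts 4, 3, 1
  rk <- attr(cf, "ranking")
  expect_equal(rk$core_count[rk$channel == "O1"], 1)
})
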