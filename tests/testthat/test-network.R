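toy_edges <- function() {
  data.frame(compound_id = c("c1", "c1", "c2", "c3"),
             target = c("A", "B", "A", "C"),
             stringsAsFactors = FALSE)
}

test_that("assembly unions edges and resolves collisions to known", {
  known <- data.frame(compound_id = c("c1", "c1", "c2"),
                      target = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  pred <- data.frame(compound_id = c("c3", "c4"), target = c("A", "B"),
                     score = c(0.2, 0.1), stringsAsFactors = FALSE)
  net <- assemble_network(known, pred)
  expect_equal(nrow(net$edges), 5)
  expect_setequal(unique(net$edges$provenance), c("known", "predicted"))

  # same edge in both lists: one edge, provenance known
  clash <- assemble_network(known,
    data.frame(compound_id = "c1", target = "A", score = 0.9,
               stringsAsFactors = FALSE))
  expect_equal(nrow(clash$edges), 3)
  e <- clash$edges[clash$edges$compound_id == "c1" & clash$edges$target == "A", ]
  expect_equal(e$provenance, "known")

  # empty predicted list: network equals the known network
  expect_equal(assemble_network(known, NULL)$edges,
               assemble_network(known)$edges)
})

test_that("degree summary computes exact means and the handshake holds", {
  net <- assemble_network(toy_edges())
  ds <- degree_summary(net)
  expect_equal(ds$n_edges, 4)
  expect_equal(ds$mean_compound_degree, 4 / 3)
  expect_equal(ds$mean_target_degree, 4 / 3)
  expect_equal(sum(ds$compound_degrees), ds$n_edges)
  expect_equal(sum(ds$target_degrees), ds$n_edges)
  # means times node counts reproduce the edge count exactly
  expect_equal(ds$mean_compound_degree * ds$n_compounds, ds$n_edges)
  expect_equal(ds$mean_target_degree * ds$n_targets, ds$n_edges)

  expect_error(degree_summary(net, provenance = "predicted"), "empty")
})

test_that("rounding of reported means is half-up at one decimal", {
  expect_equal(netpharm:::round_half_up(3.35, 1), 3.4)
  expect_equal(netpharm:::round_half_up(20.59, 1), 20.6)
  expect_equal(netpharm:::round_half_up(39.37, 1), 39.4)
  expect_equal(netpharm:::round_half_up(2.249, 1), 2.2)
})

test_that("herb overlap is symmetric with set sizes on the diagonal", {
  herbs <- data.frame(
    herb_id = c("A", "A", "B", "B"),
    compound_id = c("c1", "c2", "c2", "c3"),
    stringsAsFactors = FALSE)
  ov <- herb_overlap(herbs, "compounds")
  expect_equal(ov["A", "B"], 1L)
  expect_identical(ov, t(ov))
  expect_equal(diag(ov), c(A = 2L, B = 2L))
  expect_true(all(diag(ov) == apply(ov, 1, max)))

  net <- assemble_network(toy_edges())
  ovt <- herb_overlap(herbs, "targets", net)
  # A targets {A,B} (c1) u {A} (c2) = {A,B}; B targets {A,C}
  expect_equal(ovt["A", "B"], 1L)
  expect_equal(diag(ovt), c(A = 2L, B = 2L))
})

test_that("common targets is the all-herb intersection", {
  net <- assemble_network(data.frame(
    compound_id = paste0("c", 1:6),
    target = c("T", "T", "T", "T", "T", "T"),
    stringsAsFactors = FALSE))
  herbs <- data.frame(herb_id = paste0("H", 1:6),
                      compound_id = paste0("c", 1:6),
                      stringsAsFactors = FALSE)
  expect_equal(common_targets(herbs, net), "T")

  net2 <- assemble_network(data.frame(
    compound_id = c("c1", "c2"), target = c("A", "B"),
    stringsAsFactors = FALSE))
  herbs2 <- data.frame(herb_id = c("H1", "H2"),
                       compound_id = c("c1", "c2"),
                       stringsAsFactors = FALSE)
  expect_length(common_targets(herbs2, net2), 0)
  expect_error(common_targets(herbs2[1, ], net2), "at least 2")
})

test_that("subnetwork extraction induces the bipartite subgraph", {
  net <- assemble_network(toy_edges())
  sub <- extract_subnetwork(net, "c1")
  expect_equal(nrow(sub$edges), 2)
  expect_setequal(sub$targets, c("A", "B"))

  # extracting every compound reproduces the network
  all_sub <- extract_subnetwork(net, net$compounds)
  expect_equal(all_sub$edges, net$edges)

  expect_error(extract_subnetwork(net, character(0)), "empty")
  expect_error(extract_subnetwork(net, c("c1", "zz")), "zz")
})

test_that("high-degree nodes use a strict threshold and stable order", {
  edges <- data.frame(compound_id = paste0("c", 1:5), target = "HUB",
                      stringsAsFactors = FALSE)
  edges <- rbind(edges, data.frame(compound_id = "c1", target = "LEAF",
                                   stringsAsFactors = FALSE))
  net <- assemble_network(edges)
  hi <- high_degree_nodes(net, "targets", 4)
  expect_equal(hi$node, "HUB")
  expect_equal(nrow(high_degree_nodes(net, "targets", 5)), 0)
  all3 <- high_degree_nodes(net, "targets", 0)
  expect_equal(nrow(all3), 2)
  expect_equal(all3$node[1], "HUB")
})
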