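# The scenario model: validity, losses, vectors, costs, enumeration.

fig1_transfer_scenario <- function(inp) {
  G <- inp$gene; S <- inp$species
  a <- which(G$labels == "a"); b <- which(G$labels == "b")
  cc <- which(G$labels == "c")
  n <- G$parent[b]             # the (b,c) node
  r <- G$root
  A <- which(S$labels == "A"); B <- which(S$labels == "B")
  C <- which(S$labels == "C")
  M <- integer(G$n_node)
  M[c(a, b, cc)] <- c(A, B, C)
  M[n] <- B
  M[r] <- lca_node(S, c(A, B))
  labs <- rep("leaf", G$n_node); labs[r] <- "S"; labs[n] <- "T"
  tau <- rep(NA_integer_, G$n_node); tau[n] <- C
  dtl_scenario(M, labs, transfer_children = cc, recipients = tau)
}

fig1_duplication_scenario <- function(inp) {
  G <- inp$gene; S <- inp$species
  a <- which(G$labels == "a"); b <- which(G$labels == "b")
  cc <- which(G$labels == "c")
  n <- G$parent[b]; r <- G$root
  A <- which(S$labels == "A"); B <- which(S$labels == "B")
  C <- which(S$labels == "C")
  M <- integer(G$n_node)
  M[c(a, b, cc)] <- c(A, B, C)
  M[n] <- S$root; M[r] <- S$root
  labs <- rep("leaf", G$n_node); labs[r] <- "D"; labs[n] <- "S"
  dtl_scenario(M, labs)
}

test_that("the worked-instance scenarios validate and count their events", {
  inp <- fig1_instance()
  tr <- fig1_transfer_scenario(inp)
  expect_true(validate_scenario(inp, tr)$ok)
  expect_equal(count_losses(inp, tr)$n, 0)
  expect_equal(scenario_event_vector(inp, tr), c(0, 1, 0))

  du <- fig1_duplication_scenario(inp)
  expect_true(validate_scenario(inp, du)$ok)
  loss <- count_losses(inp, du)
  expect_equal(loss$n, 3)                  # one duplication, three losses
  expect_length(loss$events, 3)
  expect_equal(scenario_event_vector(inp, du), c(1, 0, 3))
})

test_that("constraint violations are reported by id", {
  inp <- fig1_instance()
  # leaf mapped away from its association -> constraint 1
  bad <- fig1_transfer_scenario(inp)
  a <- which(inp$gene$labels == "a")
  bad$M[a] <- which(inp$species$labels == "B")
  expect_false(validate_scenario(inp, bad)$ok)
  expect_true("1" %in% validate_scenario(inp, bad)$violations)
  # speciation with comparable child images -> 4a
  bad2 <- fig1_duplication_scenario(inp)
  bad2$labels[inp$gene$root] <- "S"
  v2 <- validate_scenario(inp, bad2)
  expect_false(v2$ok)
  expect_true("4a" %in% v2$violations)
  # transfer label without a transfer edge -> 4c
  bad3 <- fig1_duplication_scenario(inp)
  bad3$labels[inp$gene$root] <- "T"
  expect_true("4c" %in% validate_scenario(inp, bad3)$violations)
})

test_that("reconciliation cost is the exact linear form in the event counts", {
  expect_equal(as.numeric(reconciliation_cost(c(0, 1, 0), event_costs(1, 1))), 1)
  expect_equal(as.numeric(reconciliation_cost(c(1, 0, 3), event_costs(5, 1))), 4)
  expect_equal(as.numeric(reconciliation_cost(c(0, 0, 0),
                                              event_costs("3/2", "1/2"))), 0)
  expect_equal(attr(reconciliation_cost(c(1, 1, 1), event_costs("3/2", "1/2")),
                    "fraction"), "3")
  expect_error(event_costs(0, 1), "positive")
})

test_that("exhaustive enumeration agrees with hand analysis on tiny instances", {
  # 1-leaf gene tree on 1-leaf species tree: a single trivial scenario
  one <- recon_input("g;", "H;", c(g = "H"))
  sc1 <- enumerate_scenarios(one)
  expect_length(sc1, 1)
  expect_equal(sc1[[1]]$vector, c(0, 0, 0))

  inp <- fig1_instance()
  sc <- enumerate_scenarios(inp)
  vs <- unique(do.call(rbind, lapply(sc, `[[`, "vector")))
  for (v in list(c(0, 1, 0), c(0, 1, 1), c(1, 0, 3), c(0, 2, 0)))
    expect_true(any(vs[, 1] == v[1] & vs[, 2] == v[2] & vs[, 3] == v[3]),
                label = paste("vector", paste(v, collapse = ",")))
  # every enumerated scenario is valid and its loss events match its count
  for (rec in sc) {
    expect_true(validate_scenario(inp, rec$scenario)$ok)
    cl <- count_losses(inp, rec$scenario)
    expect_equal(cl$n, rec$vector[3])
    expect_length(cl$events, cl$n)
  }
  expect_error(enumerate_scenarios(recon_input(
    "(((((((a1,a2),a3),a4),a5),a6),a7),a8);", "H;",
    setNames(rep("H", 8), paste0("a", 1:8))), max_leaves = 6), "too large")
})

test_that("fixed-cost optimisation agrees between front and enumeration", {
  inp <- fig1_instance()
  expect_equal(as.numeric(min_cost_fixed(inp, event_costs(1, 1))$cost), 1)
  expect_equal(as.numeric(min_cost_fixed(inp, event_costs(5, 1))$cost), 4)
  cong <- congruent_instance(4, seed = 2)
  expect_equal(as.numeric(min_cost_fixed(cong, event_costs(2, 1))$cost), 0)
  set.seed(5)
  sims <- random_instances(4, seed = 5)
  for (sim in sims) {
    for (rep in 1:25) {
      ct <- sample(1:8, 1) / sample(1:4, 1)
      cl <- sample(1:8, 1) / sample(1:4, 1)
      costs <- event_costs(ct, cl)
      a <- min_cost_fixed(sim$input, costs, method = "front")
      b <- min_cost_fixed(sim$input, costs, method = "enumerate")
      expect_equal(as.numeric(a$cost), as.numeric(b$cost))
      expect_equal(a$count, b$count)
    }
  }
})
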