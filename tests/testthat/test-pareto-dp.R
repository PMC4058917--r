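# The Pareto-set algebra and the reconciliation dynamic program.

test_that("pareto_filter keeps exactly the maximal antichain", {
  expect_equal(pareto_filter(rbind(c(1, 1, 1), c(1, 1, 2))),
               rbind(c(1, 1, 1)))
  both <- pareto_filter(rbind(c(0, 1, 0), c(1, 0, 3)))
  expect_equal(nrow(both), 2)
  expect_equal(nrow(pareto_filter(matrix(numeric(0), 0, 3))), 0)
  # property: nothing dominated survives, everything is covered
  set.seed(3)
  for (i in 1:20) {
    v <- cbind(sample(0:4, 12, TRUE), sample(0:4, 12, TRUE),
               sample(0:8, 12, TRUE))
    f <- pareto_filter(v)
    for (a in seq_len(nrow(f)))
      for (b in seq_len(nrow(f)))
        if (a != b) expect_false(all(f[a, ] <= f[b, ]) && any(f[a, ] < f[b, ]))
    for (r in seq_len(nrow(v)))
      expect_true(any(apply(f, 1, function(x) all(x <= v[r, ]))))
  }
})

test_that("the merge adds counts and intersects events on equal vectors", {
  A <- annotated_front(rbind(c(0, 1, 0)), counts = 1, events = list("e1"))
  B <- annotated_front(rbind(c(1, 0, 3)), counts = 1, events = list("e2"))
  M <- pareto_merge(A, B)
  expect_equal(nrow(M$vec), 2)
  A2 <- annotated_front(rbind(c(1, 1, 1)), counts = 2,
                        events = list(c("x", "y")))
  B2 <- annotated_front(rbind(c(1, 1, 1)), counts = 3,
                        events = list(c("y", "z")))
  M2 <- pareto_merge(A2, B2)
  expect_equal(M2$count, 5)
  expect_equal(M2$events[[1]], "y")
  # identity
  expect_true(reconscape:::front_equal(
    pareto_merge(A, reconscape:::front_empty()),
    reconscape:::front_normalize(A)))
})

test_that("the combine equals the naive Cartesian-product oracle", {
  s1 <- annotated_front(rbind(c(0, 1, 0)))
  s2 <- annotated_front(rbind(c(1, 0, 3)))
  expect_equal(unname(pareto_combine(s1, s2)$vec), rbind(c(1, 1, 3)))
  AB <- annotated_front(rbind(c(0, 0, 1), c(0, 1, 0)))
  expect_equal(unname(pareto_combine(AB, AB)$vec),
               rbind(c(0, 0, 2), c(0, 1, 1), c(0, 2, 0)))
  # infeasibility absorbs
  expect_equal(nrow(pareto_combine(AB, reconscape:::front_empty())$vec), 0)
  # property: 250 random pairs against the independent oracle
  set.seed(42)
  for (i in 1:250) {
    A <- random_front(sample(1:10, 1))
    B <- random_front(sample(1:10, 1))
    expect_equal(unname(pareto_combine(A, B)$vec),
                 unname(naive_combine_vectors(A$vec, B$vec)))
  }
  # counts multiply per pair and add across pairs
  A <- annotated_front(rbind(c(0, 0, 1), c(0, 1, 0)), counts = c(2, 3))
  C <- pareto_combine(A, A)
  expect_equal(C$count, c(4, 12, 9))   # <0,0,2>, <0,1,1> twice, <0,2,0>
})

test_that("the DP front equals the enumeration oracle with counts and events", {
  sims <- random_instances(20, seed = 101)
  for (sim in sims) {
    fit <- pareto_reconcile(sim$input)
    orc <- oracle_summary(sim$input)
    expect_equal(unname(fit$front$vec), unname(orc$front))
    for (k in seq_len(nrow(fit$front$vec))) {
      expect_equal(fit$front$count[k], orc$annotated[[k]]$count)
      expect_true(setequal(fit$front$events[[k]], orc$annotated[[k]]$events))
    }
  }
})

test_that("fronts are antichains with at most one vector per (dup, transfer)", {
  sims <- random_instances(8, seed = 202)
  for (sim in sims) {
    v <- pareto_reconcile(sim$input, events = FALSE)$front$vec
    m <- sim$input$gene$n_tip
    # one vector per (dup, transfer) pair, each count at most m - 1 internal
    # nodes, so the front can never exceed m^2 entries
    expect_lte(nrow(v), m^2)
    expect_true(all(v[, 1] + v[, 2] <= m - 1))
    expect_equal(anyDuplicated(paste(v[, 1], v[, 2])), 0)
    for (a in seq_len(nrow(v)))
      for (b in seq_len(nrow(v)))
        if (a != b) expect_false(all(v[a, ] <= v[b, ]) && any(v[a, ] < v[b, ]))
  }
})

test_that("degenerate and congruent tanglegrams give the trivial front", {
  # single-leaf gene tree
  one <- recon_input("g;", "((A,B),C);", c(g = "B"))
  f1 <- pareto_reconcile(one)
  expect_equal(unname(f1$front$vec), rbind(c(0, 0, 0)))
  expect_equal(f1$front$count, 1)
  # congruent trees, identity mapping
  cong <- congruent_instance(5, seed = 9)
  fc <- pareto_reconcile(cong)
  expect_equal(unname(fc$front$vec), rbind(c(0, 0, 0)))
  expect_equal(fc$front$count, 1)
  # all events of the unique scenario are speciations and are all common
  expect_equal(sort(unique(substr(fc$front$events[[1]], 1, 1))), "S")
  expect_length(fc$front$events[[1]], cong$gene$n_tip - 1)
})

test_that("tracking flags change annotations, never the vector set", {
  sims <- random_instances(5, seed = 303)
  for (sim in sims) {
    a <- pareto_reconcile(sim$input, count = TRUE, events = TRUE)
    b <- pareto_reconcile(sim$input, count = FALSE, events = FALSE)
    expect_equal(unname(a$front$vec), unname(b$front$vec))
    expect_null(b$front$count)
    expect_null(b$front$events)
  }
})

test_that("the true simulated history is never better than the front", {
  sims <- random_instances(10, seed = 404, n_species = 3:5,
                           max_gene_leaves = 8)
  for (sim in sims) {
    fit <- pareto_reconcile(sim$input, events = FALSE)
    for (costs in list(event_costs(1, 1), event_costs(3, "1/2"),
                       event_costs("1/2", 2))) {
      best <- min(apply(fit$front$vec, 1,
                        function(v) as.numeric(reconciliation_cost(v, costs))))
      expect_lte(best, as.numeric(reconciliation_cost(sim$vector, costs)))
    }
  }
})
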