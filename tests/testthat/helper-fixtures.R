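# Shared fixtures and independent oracles for the property tests.

# a congruent tanglegram: identical topologies, identity tip mapping
congruent_instance <- function(n = 4, seed = 1) {
  set.seed(seed)
  sim <- simulate_cophylogeny(n, p_dup = 0, p_transfer = 0, p_loss = 0)
  sim$input
}

# random small instances with a known true history
random_instances <- function(k, seed, n_species = 3:4, max_gene_leaves = 5,
                             p_dup = 0.15, p_transfer = 0.15, p_loss = 0.1) {
  set.seed(seed)
  lapply(seq_len(k), function(i)
    simulate_cophylogeny(sample(n_species, 1), p_dup = p_dup,
                         p_transfer = p_transfer, p_loss = p_loss,
                         max_gene_leaves = max_gene_leaves))
}

# independent naive (x) oracle: full Cartesian product then Pareto filter
naive_combine_vectors <- function(A, B) {
  grid <- expand.grid(a = seq_len(nrow(A)), b = seq_len(nrow(B)))
  sums <- A[grid$a, , drop = FALSE] + B[grid$b, , drop = FALSE]
  pareto_filter(sums)
}

random_front <- function(k, vmax = 5, lmax = 8) {
  annotated_front(cbind(sample(0:vmax, k, TRUE), sample(0:vmax, k, TRUE),
                        sample(0:lmax, k, TRUE)))
}

# oracle summaries of an instance by exhaustive scenario enumeration
oracle_summary <- function(input) {
  sc <- enumerate_scenarios(input)
  vs <- do.call(rbind, lapply(sc, `[[`, "vector"))
  front <- pareto_filter(vs)
  ann <- lapply(seq_len(nrow(front)), function(i) {
    v <- front[i, ]
    hit <- which(vs[, 1] == v[1] & vs[, 2] == v[2] & vs[, 3] == v[3])
    list(vector = v, count = length(hit),
         events = Reduce(intersect, lapply(sc[hit], `[[`, "events")))
  })
  list(scenarios = sc, vectors = vs, front = front, annotated = ann)
}

# interior point of a region (mean of vertices, exact)
region_interior_point <- function(region) {
  n <- length(region$vertices)
  xs <- Reduce(reconscape:::r_add, lapply(region$vertices, `[[`, "x"))
  ys <- Reduce(reconscape:::r_add, lapply(region$vertices, `[[`, "y"))
  c(reconscape:::r_str(reconscape:::r_div(xs, reconscape:::as_rational(n))),
    reconscape:::r_str(reconscape:::r_div(ys, reconscape:::as_rational(n))))
}
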