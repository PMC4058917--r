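# Fixture generation: the minimal worked instance and a parameterized
# cophylogeny simulator used by the property tests.

#' The minimal three-leaf worked instance
#'
#' Species (host) tree `((A,B),C)`, gene (parasite) tree `(a,(b,c))`,
#' associations a-A, b-B, c-C.  The smallest tanglegram exhibiting the
#' classic cost trade-off: with cheap transfers the optimum is one
#' speciation plus one transfer (cost 1 at unit costs); with expensive
#' transfers it is one speciation, one duplication and three losses
#' (cost 4 at duplication = loss = 1, transfer = 5).
#'
#' @return a `recon_input`.
#' @examples
#' coef(pareto_reconcile(fig1_instance()))
#' @export
fig1_instance <- function() {
  recon_input("(a,(b,c));", "((A,B),C);",
              c(a = "A", b = "B", c = "C"))
}

# grow a uniformly random binary topology by successive random joins
random_species_tree <- function(n) {
  labels <- sprintf("S%d", seq_len(n))
  total <- 2L * n - 1L
  parent <- rep(NA_integer_, total)
  children <- matrix(NA_integer_, total, 2)
  labs <- c(labels, rep(NA_character_, n - 1L))
  roots <- seq_len(n)
  nxt <- n + 1L
  while (length(roots) > 1) {
    pick <- sample(length(roots), 2)
    children[nxt, ] <- roots[pick]
    parent[roots[pick]] <- nxt
    roots <- c(roots[-pick], nxt)
    nxt <- nxt + 1L
  }
  new_rb_tree(parent, children, labs, roots)
}

#' Simulate a cophylogenetic instance with a known event history
#'
#' Grows a random species tree, then evolves a gene (parasite) lineage down
#' it: at every species branch the lineage may be lost, duplicate in place,
#' or transfer one copy to a uniformly chosen incomparable species branch;
#' otherwise it co-diverges at speciations and becomes an extant tip at
#' species leaves.  Dead lineages are pruned; draws whose gene tree ends up
#' with fewer than 2 tips (or more than `max_gene_leaves`) are rejected and
#' resampled.  The realized history is returned as a valid DTL scenario of
#' the pruned instance (with transfer recipients canonicalized), giving a
#' known upper-bound reconciliation for property tests.
#'
#' @param n_species number of species tips (default 6).
#' @param p_dup,p_transfer,p_loss per-branch event probabilities
#'   (defaults 0.1 each; their sum must be at most 1).
#' @param seed optional RNG seed.
#' @param max_gene_leaves reject instances with more gene tips than this.
#' @param max_tries rejection-sampling cap.
#' @return an object of class `sim_result`: `input` (`recon_input`),
#'   `scenario` (the true history as a `dtl_scenario`), `vector` (its event
#'   count vector) and `events` (its event keys).
#' @examples
#' sim <- simulate_cophylogeny(4, seed = 42)
#' sim$vector
#' @export
simulate_cophylogeny <- function(n_species = 6, p_dup = 0.1,
                                 p_transfer = 0.1, p_loss = 0.1,
                                 seed = NULL, max_gene_leaves = Inf,
                                 max_tries = 1000) {
  stopifnot(n_species >= 2, p_dup >= 0, p_transfer >= 0, p_loss >= 0,
            p_dup + p_transfer + p_loss <= 1)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    res <- sim_once(n_species, p_dup, p_transfer, p_loss, max_gene_leaves)
    if (!is.null(res)) return(res)
  }
  stop("simulation did not produce a usable instance in ", max_tries,
       " tries")
}

sim_once <- function(n_species, p_dup, p_transfer, p_loss,
                     max_gene_leaves) {
  S <- random_species_tree(n_species)
  depth_cap <- 500L
  evolve <- function(s, depth) {
    if (depth > depth_cap) stop("simulation recursion too deep")
    inc <- which(vapply(seq_len(S$n_node), function(x)
      incomparable(S, s, x), logical(1)))
    u <- stats::runif(1)
    if (u < p_loss) return(list(type = "dead"))
    if (u < p_loss + p_dup)
      return(list(type = "D", s = s,
                  kids = list(evolve(s, depth + 1), evolve(s, depth + 1))))
    if (u < p_loss + p_dup + p_transfer && length(inc) > 0) {
      x <- inc[sample.int(length(inc), 1)]
      return(list(type = "T", s = s,
                  kids = list(evolve(s, depth + 1), evolve(x, depth + 1))))
    }
    if (S$is_tip[s]) return(list(type = "leaf", s = s))
    list(type = "S", s = s,
         kids = list(evolve(S$children[s, 1], depth + 1),
                     evolve(S$children[s, 2], depth + 1)))
  }
  full <- tryCatch(evolve(S$root, 1L), error = function(e) NULL)
  if (is.null(full)) return(NULL)
  pruned <- prune_dead(full)
  if (is.null(pruned)) return(NULL)
  n_leaves <- count_leaves(pruned)
  if (n_leaves < 2 || n_leaves > max_gene_leaves) return(NULL)
  build_sim_result(pruned, S)
}

prune_dead <- function(node) {
  if (node$type == "dead") return(NULL)
  if (node$type == "leaf") return(node)
  kids <- lapply(node$kids, prune_dead)
  alive <- !vapply(kids, is.null, logical(1))
  if (!any(alive)) return(NULL)
  if (sum(alive) == 1) return(kids[alive][[1]])  # pass-through
  node$kids <- kids
  node
}

count_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  sum(vapply(node$kids, count_leaves, integer(1)))
}

build_sim_result <- function(root, S) {
  if (root$type == "leaf") return(NULL)
  n_tip <- count_leaves(root)
  total <- 2L * n_tip - 1L
  parent <- rep(NA_integer_, total)
  children <- matrix(NA_integer_, total, 2)
  labs <- rep(NA_character_, total)
  M <- rep(NA_integer_, total)
  per_host <- new.env()
  nxt <- new.env(); nxt$tip <- 0L; nxt$int <- n_tip
  assign_ids <- function(node) {
    if (node$type == "leaf") {
      nxt$tip <- nxt$tip + 1L
      id <- nxt$tip
      host <- S$labels[node$s]
      k <- (get0(host, envir = per_host, ifnotfound = 0L)) + 1L
      assign(host, k, envir = per_host)
      labs[id] <<- paste0(tolower(host), "_", k)
      M[id] <<- node$s
      return(id)
    }
    nxt$int <- nxt$int + 1L
    id <- nxt$int
    k1 <- assign_ids(node$kids[[1]])
    k2 <- assign_ids(node$kids[[2]])
    children[id, ] <<- c(k1, k2)
    parent[c(k1, k2)] <<- id
    M[id] <<- node$s
    id
  }
  root_id <- assign_ids(root)
  G <- new_rb_tree(parent, children, labs, root_id)
  mapping <- stats::setNames(S$labels[M[seq_len(n_tip)]],
                             labs[seq_len(n_tip)])
  input <- recon_input(G, S, mapping)
  # derive the scenario labels from the pruned topology: transfer edges are
  # forced by incomparability; remaining nodes are speciations where
  # eligible, otherwise duplications
  labels <- rep("leaf", total)
  xi <- integer(0)
  tau <- rep(NA_integer_, total)
  for (t in which(!G$is_tip)) {
    ch <- G$children[t, ]
    inc <- vapply(ch, function(cc) incomparable(S, M[t], M[cc]), logical(1))
    if (sum(inc) > 1) return(NULL)  # whole subtree emigrated: not a scenario
    if (sum(inc) == 1) {
      tc <- ch[inc]
      labels[t] <- "T"
      xi <- c(xi, tc)
      tau[t] <- M[tc]
    } else {
      l <- lca_node(S, M[ch])
      if (M[t] == l && incomparable(S, M[ch[1]], M[ch[2]]))
        labels[t] <- "S"
      else labels[t] <- "D"
    }
  }
  scen <- dtl_scenario(M, labels, xi, tau)
  chk <- validate_scenario(input, scen)
  # multi-hop transfer chains can occasionally strand a lineage above its
  # parent's mapping after pruning; such draws are not DTL scenarios of the
  # pruned instance and are rejected like dead gene trees
  if (!chk$ok) return(NULL)
  structure(list(input = input, scenario = scen,
                 vector = scenario_event_vector(input, scen),
                 events = scenario_events(input, scen)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated cophylogeny instance\n")
  print(x$input)
  cat("  true event vector: <", paste(x$vector, collapse = ","), ">\n",
      sep = "")
  invisible(x)
}

#' Write a simulated instance to fixture files
#'
#' Writes `<prefix>.host.nwk`, `<prefix>.parasite.nwk`,
#' `<prefix>.mapping.tsv` and `<prefix>.log.json` (the true scenario).
#'
#' @param sim a `sim_result`.
#' @param prefix output path prefix.
#' @return the four file paths, invisibly.
#' @export
write_sim_result <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_result"))
  paths <- paste0(prefix, c(".host.nwk", ".parasite.nwk", ".mapping.tsv",
                            ".log.json"))
  writeLines(write_newick(sim$input$species), paths[1])
  writeLines(write_newick(sim$input$gene), paths[2])
  writeLines(paste(names(sim$input$mapping), unname(sim$input$mapping),
                   sep = "\t"), paths[3])
  log <- list(vector = sim$vector, events = sim$events,
              mapping = sim$scenario$M, labels = sim$scenario$labels,
              transfer_children = sim$scenario$xi)
  jsonlite::write_json(log, paths[4], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
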