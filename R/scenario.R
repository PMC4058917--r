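# The DTL-scenario model: explicit reconciliation scenarios, validity
# checking, loss counting, event vectors, reconciliation cost, and an
# exhaustive enumeration used as a correctness oracle on tiny instances.
#
# A scenario maps every gene node to a species node, labels every internal
# gene node as speciation ("S"), duplication ("D") or transfer ("T"),
# records the set of transfer edges (by the child endpoint) and the
# recipient species of each transfer.  Transfer recipients follow the
# canonical zero-distance convention: the recipient is the species node the
# transferred child maps to.  Non-canonical recipients only add losses and
# are strictly dominated, and the dynamic program never pays them.

#' Construct a DTL scenario
#'
#' @param mapping integer vector, gene node id -> species node id.
#' @param labels character vector over gene node ids: `"leaf"` for tips,
#'   `"S"`, `"D"` or `"T"` for internal nodes.
#' @param transfer_children integer vector of gene nodes whose parent edge
#'   is a transfer edge.
#' @param recipients integer vector over gene node ids: recipient species of
#'   each transfer node, `NA` elsewhere.
#' @return an object of class `dtl_scenario`.
#' @export
dtl_scenario <- function(mapping, labels, transfer_children = integer(0),
                         recipients = rep(NA_integer_, length(mapping))) {
  structure(list(M = as.integer(mapping), labels = labels,
                 xi = as.integer(transfer_children),
                 tau = as.integer(recipients)),
            class = "dtl_scenario")
}

#' @export
print.dtl_scenario <- function(x, ...) {
  cat("DTL scenario:",
      sum(x$labels == "S"), "speciations,",
      sum(x$labels == "D"), "duplications,",
      sum(x$labels == "T"), "transfers\n")
  invisible(x)
}

#' Check a scenario against the DTL validity constraints
#'
#' Verifies the defining constraints of a DTL scenario: leaf consistency
#' (1), the temporal constraints on the internal mapping (2a, 2b), the
#' characterization of transfer edges (3), and the event-label conditions
#' (4a speciation, 4b duplication, 4c transfer, 4d recipient).
#'
#' @param input a `recon_input`.
#' @param scenario a `dtl_scenario`.
#' @return list with `ok` (logical) and `violations` (character vector of
#'   constraint ids among `1`, `2a`, `2b`, `3`, `4a`, `4b`, `4c`, `4d`).
#' @export
validate_scenario <- function(input, scenario) {
  G <- input$gene; S <- input$species
  M <- scenario$M
  if (length(M) != G$n_node || any(is.na(M)) || any(M < 1 | M > S$n_node))
    stop("scenario mapping does not cover the gene tree")
  viol <- character(0)
  add <- function(id) viol <<- unique(c(viol, id))
  for (t in which(G$is_tip))
    if (M[t] != input$leaf_map[t]) add("1")
  for (t in which(!G$is_tip)) {
    c1 <- G$children[t, 1]; c2 <- G$children[t, 2]
    # 2a: M(t) may not be a proper descendant of a child's image
    if ((S$anc[M[t], M[c1]] && M[t] != M[c1]) ||
        (S$anc[M[t], M[c2]] && M[t] != M[c2])) add("2a")
    # 2b: at least one child image is a descendant of M(t)
    if (!S$anc[M[c1], M[t]] && !S$anc[M[c2], M[t]]) add("2b")
    # 3: transfer edges are exactly the edges with incomparable images
    for (ch in c(c1, c2)) {
      inc <- incomparable(S, M[t], M[ch])
      if (inc != (ch %in% scenario$xi)) add("3")
    }
    lab <- scenario$labels[t]
    if (!lab %in% c("S", "D", "T")) stop("internal node ", t, " unlabeled")
    if (lab == "S") {
      l <- lca_node(S, c(M[c1], M[c2]))
      if (M[t] != l || !incomparable(S, M[c1], M[c2])) add("4a")
    } else if (lab == "D") {
      l <- lca_node(S, c(M[c1], M[c2]))
      if (!S$anc[l, M[t]]) add("4b")
    }
    has_te <- any(c(c1, c2) %in% scenario$xi)
    if ((lab == "T") != has_te) add("4c")
    if (lab == "T") {
      tc <- intersect(c(c1, c2), scenario$xi)
      tau <- scenario$tau[t]
      if (length(tc) != 1 || is.na(tau) ||
          !incomparable(S, M[t], tau) || !S$anc[M[tc[1]], tau]) add("4d")
    }
  }
  list(ok = length(viol) == 0, violations = sort(viol))
}

# loss events along a species path: the lineage above gene node `gnode`
# enters species node `from` and continues down to `to`; at every node
# where it continues into one child, a loss occurs on the other child edge.
# With `skip_first` the divergence at `from` itself is not a loss (the
# speciation case).
loss_path <- function(S, gnode, from, to, skip_first = FALSE) {
  ev <- character(0)
  cur <- from
  if (skip_first && cur != to) {
    ch <- S$children[cur, ]
    cur <- if (S$anc[to, ch[1]]) ch[1] else ch[2]
  }
  while (cur != to) {
    ch <- S$children[cur, ]
    nxt <- if (S$anc[to, ch[1]]) ch[1] else ch[2]
    lost <- ch[ch != nxt]
    ev <- c(ev, paste0("L:", gnode, "|", cur, ">", lost))
    cur <- nxt
  }
  ev
}

#' Count the losses of a valid DTL scenario
#'
#' Applies the per-node loss formula: a speciation at `s` with children
#' mapped at distance `d1`, `d2` contributes `|d1-1| + |d2-1|`, a
#' duplication `d1 + d2`, and a transfer the distance of the staying child
#' plus the distance from the recipient to the transferred child's image.
#' Each loss is also materialized as an event located on a gene branch and a
#' species branch.
#'
#' @param input a `recon_input`.
#' @param scenario a valid `dtl_scenario`.
#' @return list with `n` (total loss count) and `events` (character vector
#'   of loss event keys, one per loss).
#' @export
count_losses <- function(input, scenario) {
  chk <- validate_scenario(input, scenario)
  if (!chk$ok)
    stop("invalid scenario (constraints ",
         paste(chk$violations, collapse = ", "), ")")
  G <- input$gene; S <- input$species
  M <- scenario$M
  ev <- character(0)
  for (t in which(!G$is_tip)) {
    c1 <- G$children[t, 1]; c2 <- G$children[t, 2]
    lab <- scenario$labels[t]
    if (lab == "S") {
      ev <- c(ev, loss_path(S, c1, M[t], M[c1], skip_first = TRUE),
              loss_path(S, c2, M[t], M[c2], skip_first = TRUE))
    } else if (lab == "D") {
      ev <- c(ev, loss_path(S, c1, M[t], M[c1]),
              loss_path(S, c2, M[t], M[c2]))
    } else {
      tc <- intersect(c(c1, c2), scenario$xi)[1]
      st <- setdiff(c(c1, c2), tc)[1]
      ev <- c(ev, loss_path(S, st, M[t], M[st]),
              loss_path(S, tc, scenario$tau[t], M[tc]))
    }
  }
  list(n = length(ev), events = ev)
}

# full event set of a valid scenario (speciations, duplications, transfers,
# losses), in the same key encoding the dynamic program uses
scenario_events <- function(input, scenario) {
  G <- input$gene
  ev <- count_losses(input, scenario)$events
  for (t in which(!G$is_tip)) {
    lab <- scenario$labels[t]
    s <- scenario$M[t]
    if (lab == "S") ev <- c(ev, paste0("S:", t, "|", s))
    else if (lab == "D") ev <- c(ev, paste0("D:", t, "|", s))
    else {
      tc <- intersect(G$children[t, ], scenario$xi)[1]
      ev <- c(ev, paste0("T:", t, ">", tc, "|", s, "->", scenario$tau[t]))
    }
  }
  sort(ev)
}

#' Event count vector of a valid scenario
#'
#' @param input a `recon_input`.
#' @param scenario a valid `dtl_scenario`.
#' @return numeric vector `c(duplications, transfers, losses)`.
#' @export
scenario_event_vector <- function(input, scenario) {
  c(sum(scenario$labels == "D"),
    sum(scenario$labels == "T"),
    count_losses(input, scenario)$n)
}

#' Event costs
#'
#' Speciation is the null event with cost 0; duplication, transfer and loss
#' have strictly positive costs.  In normalized mode (the default
#' throughout the cost-space analyses) duplication cost is 1 and transfer
#' and loss are relative to it.  Values may be numerics or exact fraction
#' strings like `"3/2"`.
#'
#' @param transfer,loss,duplication positive costs.
#' @return an object of class `event_costs`.
#' @export
event_costs <- function(transfer = 1, loss = 1, duplication = 1) {
  cd <- as_rational(duplication)
  ct <- as_rational(transfer)
  cl <- as_rational(loss)
  for (x in list(cd, ct, cl))
    if (x[1] <= 0) stop("event costs must be strictly positive")
  structure(list(dup = cd, transfer = ct, loss = cl), class = "event_costs")
}

#' @export
print.event_costs <- function(x, ...) {
  cat("Event costs: duplication ", r_str(x$dup), ", transfer ",
      r_str(x$transfer), ", loss ", r_str(x$loss), ", speciation 0\n",
      sep = "")
  invisible(x)
}

# exact rational cost of a vector at given costs
cost_rational <- function(vector, costs) {
  r_add(r_mul(as_rational(vector[1]), costs$dup),
        r_add(r_mul(as_rational(vector[2]), costs$transfer),
              r_mul(as_rational(vector[3]), costs$loss)))
}

#' Reconciliation cost of an event count vector
#'
#' `duplications * C_dup + transfers * C_transfer + losses * C_loss`,
#' computed in exact rational arithmetic.
#'
#' @param vector numeric vector `c(duplications, transfers, losses)`.
#' @param costs an `event_costs` object.
#' @return numeric cost, with the exact value as a `"fraction"` attribute.
#' @export
reconciliation_cost <- function(vector, costs) {
  if (!inherits(costs, "event_costs")) stop("costs must be event_costs")
  r <- cost_rational(vector, costs)
  structure(r_num(r), fraction = r_str(r))
}

#' Exhaustively enumerate all DTL scenarios of a tiny instance
#'
#' Every distinct valid scenario under the canonical-recipient convention,
#' obtained by enumerating internal-node mappings compatible with the
#' temporal constraints and then all admissible event labelings (a node
#' whose children's images are incomparable with the mapping at their LCA
#' may be labeled either speciation or duplication; both labelings are
#' distinct scenarios).  Intended purely as a correctness oracle.
#'
#' @param input a `recon_input`.
#' @param max_leaves refuse instances with more leaves than this on either
#'   tree (default 6).
#' @return list of records, each with `scenario`, `vector` and `events`.
#' @export
enumerate_scenarios <- function(input, max_leaves = 6) {
  G <- input$gene; S <- input$species
  if (G$n_tip > max_leaves || S$n_tip > max_leaves)
    stop("instance too large for exhaustive enumeration (cap ",
         max_leaves, " leaves)")
  internals <- G$postorder[!G$is_tip[G$postorder]]  # children first
  M0 <- rep(NA_integer_, G$n_node)
  M0[G$is_tip] <- input$leaf_map[G$is_tip]
  maps <- list(M0)
  for (t in internals) {
    c1 <- G$children[t, 1]; c2 <- G$children[t, 2]
    nxt <- list()
    for (M in maps) {
      for (s in seq_len(S$n_node)) {
        # 2a: s not a proper descendant of a child's image
        if (S$anc[s, M[c1]] && s != M[c1]) next
        if (S$anc[s, M[c2]] && s != M[c2]) next
        # 2b: at least one child image below s
        if (!S$anc[M[c1], s] && !S$anc[M[c2], s]) next
        M2 <- M; M2[t] <- s
        nxt[[length(nxt) + 1L]] <- M2
      }
    }
    maps <- nxt
  }
  out <- list()
  for (M in maps) {
    labs <- rep("leaf", G$n_node)
    xi <- integer(0)
    tau <- rep(NA_integer_, G$n_node)
    choice <- list()   # per dual-eligible node, both labels
    for (t in internals) {
      ch <- G$children[t, ]
      inc <- vapply(ch, function(cc) incomparable(S, M[t], M[cc]), logical(1))
      if (any(inc)) {
        tc <- ch[inc][1]
        labs[t] <- "T"
        xi <- c(xi, tc)
        tau[t] <- M[tc]
      } else {
        l <- lca_node(S, M[ch])
        sig_ok <- (M[t] == l) && incomparable(S, M[ch[1]], M[ch[2]])
        if (sig_ok) choice[[as.character(t)]] <- c("S", "D")
        else labs[t] <- "D"
      }
    }
    free <- names(choice)
    grids <- if (length(free)) expand.grid(choice, stringsAsFactors = FALSE)
             else data.frame(row.names = 1)
    for (r in seq_len(nrow(grids))) {
      labs2 <- labs
      for (nm in free) labs2[as.integer(nm)] <- grids[r, nm]
      sc <- dtl_scenario(M, labs2, xi, tau)
      out[[length(out) + 1L]] <- list(
        scenario = sc,
        vector = scenario_event_vector(input, sc),
        events = scenario_events(input, sc))
    }
  }
  out
}

#' Minimum reconciliation cost at fixed event costs
#'
#' The optimum of the reconciliation cost over all valid scenarios, plus the
#' number of scenarios attaining it.  With positive costs every optimal
#' scenario's vector lies on the Pareto front, so the default route
#' evaluates the front; the enumeration route is an independent brute-force
#' check for tiny instances.
#'
#' @param input a `recon_input`.
#' @param costs an `event_costs`.
#' @param method `"front"` (default) or `"enumerate"`.
#' @return list with `cost` (numeric, exact fraction as attribute), `count`
#'   (number of optimal scenarios) and `vectors` (matrix of the optimal
#'   event count vectors).
#' @export
min_cost_fixed <- function(input, costs, method = c("front", "enumerate")) {
  method <- match.arg(method)
  if (!inherits(costs, "event_costs")) stop("costs must be event_costs")
  if (method == "front") {
    fit <- pareto_reconcile(input, events = FALSE)
    vec <- fit$front$vec
    cs <- lapply(seq_len(nrow(vec)), function(i) cost_rational(vec[i, ], costs))
    best <- Reduce(function(a, b) if (r_le(a, b)) a else b, cs)
    opt <- vapply(cs, function(c) r_eq(c, best), logical(1))
    list(cost = structure(r_num(best), fraction = r_str(best)),
         count = sum(fit$front$count[opt]),
         vectors = vec[opt, , drop = FALSE])
  } else {
    sc <- enumerate_scenarios(input)
    cs <- lapply(sc, function(x) cost_rational(x$vector, costs))
    best <- Reduce(function(a, b) if (r_le(a, b)) a else b, cs)
    opt <- vapply(cs, function(c) r_eq(c, best), logical(1))
    vec <- unique(do.call(rbind, lapply(sc[opt], `[[`, "vector")))
    list(cost = structure(r_num(best), fraction = r_str(best)),
         count = sum(opt),
         vectors = vec)
  }
}
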