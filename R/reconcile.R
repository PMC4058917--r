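# The Pareto-front reconciliation dynamic program.
#
# A nested post-order traversal of the gene tree T and the species tree S
# computes, for every pair (t, s), the annotated Pareto set of event count
# vectors for reconciling T(t) with S such that t maps to s, split by the
# event at t (speciation / duplication / transfer).  Auxiliary tables reuse
# work across species nodes:
#
#   in(t, s)    — best fronts with t mapping anywhere in S(s), paying one
#                 loss per edge descended below s,
#   inAlt(t, s) — as in(t, s) but without the loss charges (used to seed
#                 out), and
#   out(t, s)   — best fronts with t mapping to any species node
#                 incomparable to s (the transfer landing sites).
#
# Infeasible cells are empty fronts: the merge identity and the combine
# absorber.  out(t, rt(S)) is always empty — nothing is incomparable to the
# root, so transfers at the species root are impossible.  out is computed
# for every gene node including leaves, since the transfer recurrence at an
# internal node consumes out at its children.

#' Compute all Pareto-optimal event count vectors of a reconciliation
#'
#' Fits the Pareto front of the duplication-transfer-loss reconciliation of
#' a gene (parasite) tree into a species (host) tree: the complete antichain
#' of event count vectors \eqn{\langle\delta,\theta,\ell\rangle} such that
#' no valid reconciliation is componentwise at least as good and strictly
#' better somewhere.  Each vector is annotated with the number of distinct
#' maximum-parsimony reconciliations achieving it and, when `events = TRUE`,
#' the set of events (speciations, duplications, transfers with their
#' recipients, losses on specific branch pairs) common to every one of
#' them.
#'
#' @param input a `recon_input` (see [recon_input()]), or a gene tree if
#'   `species` and `mapping` are given.
#' @param species,mapping optional: species tree and tip mapping, to build
#'   the instance in place.
#' @param count keep per-vector reconciliation counts in the result
#'   (they are always computed; `FALSE` drops them).
#' @param events track per-vector common-event sets (disable to restore the
#'   untracked complexity bound).
#' @return an object of class `pareto_recon` with the annotated front.
#' @examples
#' fit <- pareto_reconcile(fig1_instance())
#' summary(fit)
#' @export
pareto_reconcile <- function(input, species = NULL, mapping = NULL,
                             count = TRUE, events = TRUE) {
  if (!inherits(input, "recon_input"))
    input <- recon_input(input, species, mapping)
  G <- input$gene; S <- input$species
  nS <- S$n_node
  te <- isTRUE(events)
  EMPTY <- front_empty(te)
  ix <- function(t, s) (t - 1L) * nS + s
  Pt <- INt <- INALTt <- OUTt <- rep(list(EMPTY), G$n_node * nS)

  transfer_front <- function(stay, move, s) {
    # ((in(stay,s) (x) out(move,s)) with the transfer edge (t, move);
    # the transfer event needs a unique recipient on the out side
    A <- INt[[ix(stay, s)]]
    B <- OUTt[[ix(move, s)]]
    hook <- NULL
    if (te) {
      t <- G$parent[move]
      hook <- function(i, j) {
        tops <- B$tops[[j]]
        if (length(tops) == 1)
          paste0("T:", t, ">", move, "|", s, "->", tops)
        else character(0)
      }
    }
    pareto_combine(A, B, pair_events = hook)
  }

  for (t in G$postorder) {
    if (G$is_tip[t]) {
      s0 <- input$leaf_map[t]
      Pt[[ix(t, s0)]] <- front_unit(te, tops = s0)
    } else {
      t1 <- G$children[t, 1]; t2 <- G$children[t, 2]
      for (s in S$postorder) {
        PT <- if (s != S$root)
          front_shift(pareto_merge(transfer_front(t1, t2, s),
                                   transfer_front(t2, t1, s)), "T", 1)
        else EMPTY
        if (S$is_tip[s]) {
          PD <- front_shift(pareto_combine(Pt[[ix(t1, s)]], Pt[[ix(t2, s)]]),
                            "D", 1, event = paste0("D:", t, "|", s))
          P <- pareto_merge(PD, PT)
        } else {
          s1 <- S$children[s, 1]; s2 <- S$children[s, 2]
          PS <- pareto_merge(
            pareto_combine(INt[[ix(t1, s1)]], INt[[ix(t2, s2)]]),
            pareto_combine(INt[[ix(t2, s1)]], INt[[ix(t1, s2)]]))
          PS <- front_add_event(PS, paste0("S:", t, "|", s))
          PD <- front_shift(pareto_combine(INt[[ix(t1, s)]], INt[[ix(t2, s)]]),
                            "D", 1, event = paste0("D:", t, "|", s))
          P <- pareto_merge(pareto_merge(PS, PD), PT)
        }
        Pt[[ix(t, s)]] <- front_set_tops(P, s)
      }
    }
    # in / inAlt over S in post-order (gene leaves included)
    for (s in S$postorder) {
      if (S$is_tip[s]) {
        INt[[ix(t, s)]] <- Pt[[ix(t, s)]]
        INALTt[[ix(t, s)]] <- Pt[[ix(t, s)]]
      } else {
        s1 <- S$children[s, 1]; s2 <- S$children[s, 2]
        INt[[ix(t, s)]] <- pareto_merge(
          Pt[[ix(t, s)]],
          pareto_merge(
            front_shift(INt[[ix(t, s1)]], "L", 1,
                        event = paste0("L:", t, "|", s, ">", s2)),
            front_shift(INt[[ix(t, s2)]], "L", 1,
                        event = paste0("L:", t, "|", s, ">", s1))))
        INALTt[[ix(t, s)]] <- pareto_merge(
          Pt[[ix(t, s)]],
          pareto_merge(INALTt[[ix(t, s1)]], INALTt[[ix(t, s2)]]))
      }
    }
    # out over S in pre-order; out(t, rt(S)) stays empty
    for (s in S$preorder) {
      if (!S$is_tip[s]) {
        s1 <- S$children[s, 1]; s2 <- S$children[s, 2]
        OUTt[[ix(t, s1)]] <- pareto_merge(OUTt[[ix(t, s)]],
                                          INALTt[[ix(t, s2)]])
        OUTt[[ix(t, s2)]] <- pareto_merge(OUTt[[ix(t, s)]],
                                          INALTt[[ix(t, s1)]])
      }
    }
  }
  front <- Reduce(pareto_merge,
                  lapply(seq_len(nS), function(s) Pt[[ix(G$root, s)]]),
                  EMPTY)
  front$tops <- NULL
  if (!isTRUE(count)) front$count <- NULL
  structure(list(front = front, input = input,
                 count = isTRUE(count), events = te),
            class = "pareto_recon")
}

#' @export
print.pareto_recon <- function(x, ...) {
  k <- front_size(x$front)
  cat("Pareto-optimal DTL reconciliation front:", k,
      if (k == 1) "vector\n" else "vectors\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.pareto_recon <- function(object, ...) {
  v <- object$front$vec
  colnames(v) <- c("duplications", "transfers", "losses")
  rownames(v) <- NULL
  v
}

#' @export
summary.pareto_recon <- function(object, ...) {
  v <- object$front$vec
  m <- object$input$gene$n_tip
  df <- data.frame(
    duplications = v[, 1], transfers = v[, 2], losses = v[, 3],
    speciations = (m - 1) - v[, 1] - v[, 2])
  if (!is.null(object$front$count)) df$count <- object$front$count
  if (object$events)
    df$common_events <- vapply(object$front$events, length, integer(1))
  structure(list(table = df, n_tip_gene = m,
                 n_tip_species = object$input$species$n_tip),
            class = "summary.pareto_recon")
}

#' @export
print.summary.pareto_recon <- function(x, ...) {
  cat("DTL Pareto front for", x$n_tip_gene, "gene tips on",
      x$n_tip_species, "species tips\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pareto_recon <- function(x, box = cost_box(0.1, 5, 0.1, 5), ...) {
  plot(cost_regions(x, box), ...)
}

#' Human-readable description of event keys
#'
#' Event keys are compact strings over internal node ids; this expands them
#' to labels using tip names (internal nodes are named by a pair of extreme
#' descendant tips).
#'
#' @param input the `recon_input` the events refer to.
#' @param keys character vector of event keys.
#' @return character vector of descriptions.
#' @export
describe_events <- function(input, keys) {
  G <- input$gene; S <- input$species
  vapply(keys, function(k) {
    kind <- substr(k, 1, 1)
    body <- substring(k, 3)
    if (kind == "T") {
      m <- regmatches(body, regexec("^(\\d+)>(\\d+)\\|(\\d+)->(\\d+)$", body))[[1]]
      sprintf("transfer %s (edge to %s) from %s to %s",
              node_name(G, as.integer(m[2])), node_name(G, as.integer(m[3])),
              node_name(S, as.integer(m[4])), node_name(S, as.integer(m[5])))
    } else if (kind == "L") {
      m <- regmatches(body, regexec("^(\\d+)\\|(\\d+)>(\\d+)$", body))[[1]]
      sprintf("loss on gene branch above %s at species branch %s->%s",
              node_name(G, as.integer(m[2])), node_name(S, as.integer(m[3])),
              node_name(S, as.integer(m[4])))
    } else {
      m <- regmatches(body, regexec("^(\\d+)\\|(\\d+)$", body))[[1]]
      sprintf("%s %s at %s",
              if (kind == "S") "speciation" else "duplication",
              node_name(G, as.integer(m[2])), node_name(S, as.integer(m[3])))
    }
  }, character(1), USE.NAMES = FALSE)
}
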