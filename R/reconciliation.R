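# Event-cost parsimony reconciliation of a rooted binary gene tree against a
# rooted binary species tree under the undated duplication-transfer-loss
# (DTL) model. Dynamic programming over (gene node x species node): at each
# gene node the cheapest of speciation, duplication or transfer is taken,
# with one loss charged per species branch skipped on a descent path.
# Transfers are allowed between any two branches not in an ancestor-
# descendant relation; global time consistency across transfers is not
# enforced.
#
# c(u, x)   cheapest cost of the gene subtree at u with u's event at species
#           node x
# in(u, x)  cheapest cost of u entering at the top of branch x and resolving
#           at x or anywhere below (losses charged per skipped branch)
# out(u, x) min of in(u, x'') over all x'' incomparable with x (transfer
#           recipients)
#
# Ties are broken deterministically: speciation > duplication > transfer,
# then lowest canonical species-branch id (children ordered by smallest
# descendant leaf label, preorder numbering).

COST_TOL <- 1e-9

#' DTL event costs
#'
#' @param loss,duplication,transfer non-negative event costs. Defaults
#'   loss = 1, duplication = 2, transfer (HGT) = 3; speciation is free.
#'   `transfer = Inf` disables transfers (duplication-loss model).
#' @export
event_costs <- function(loss = 1.0, duplication = 2.0, transfer = 3.0) {
  stopifnot(loss >= 0, duplication >= 0, transfer >= 0)
  structure(list(loss = loss, duplication = duplication, transfer = transfer),
            class = "event_costs")
}

# Canonical indexed form of a rooted binary ape tree. Node ids are assigned
# in preorder with children visited in order of their smallest descendant
# leaf label, so ids are invariant to input rotation.
tree_index <- function(phy, what = "tree") {
  if (!inherits(phy, "phylo")) stop(what, " must be a phylo object", call. = FALSE)
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("non-binary: ", what, " must be rooted and strictly bifurcating",
         call. = FALSE)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  kids_ape <- vector("list", nnode)
  for (i in seq_len(nrow(phy$edge)))
    kids_ape[[phy$edge[i, 1L]]] <- c(kids_ape[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  root_ape <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  minleaf <- character(nnode)
  fill_minleaf <- function(v) {
    if (v <= ntip) { minleaf[v] <<- phy$tip.label[v]; return(minleaf[v]) }
    minleaf[v] <<- min(vapply(kids_ape[[v]], fill_minleaf, character(1)))
    minleaf[v]
  }
  fill_minleaf(root_ape)
  # preorder with canonical child order
  id_of <- integer(nnode); order_seq <- integer(0)
  assign_ids <- function(v) {
    id_of[v] <<- length(order_seq) + 1L
    order_seq <<- c(order_seq, v)
    if (v > ntip)
      for (k in kids_ape[[v]][order(minleaf[kids_ape[[v]]])]) assign_ids(k)
  }
  assign_ids(root_ape)
  n <- nnode
  parent <- integer(n); parent[] <- NA_integer_
  children <- vector("list", n)
  labels <- character(n); is_leaf <- logical(n); depth <- integer(n)
  for (v in order_seq) {
    id <- id_of[v]
    is_leaf[id] <- v <= ntip
    if (v <= ntip) labels[id] <- phy$tip.label[v]
    else {
      lbl <- if (!is.null(phy$node.label) && length(phy$node.label) >= v - ntip)
        phy$node.label[v - ntip] else NA_character_
      labels[id] <- if (!is.na(lbl) && nzchar(lbl)) lbl else paste0("N", id)
    }
    if (v > ntip)
      children[[id]] <- sort(id_of[kids_ape[[v]]])
  }
  for (id in seq_len(n)) for (k in children[[id]]) parent[k] <- id
  root <- id_of[root_ape]
  depth[root] <- 0L
  pre <- id_of[order_seq]  # ids in preorder
  for (id in pre[-1L]) depth[id] <- depth[parent[id]] + 1L
  post <- rev(pre)
  desc <- matrix(FALSE, n, n)  # desc[x, y]: y in subtree of x (or y == x)
  for (x in post) {
    desc[x, x] <- TRUE
    for (k in children[[x]]) desc[x, ] <- desc[x, ] | desc[k, ]
  }
  list(n = n, root = root, parent = parent, children = children,
       labels = labels, is_leaf = is_leaf, depth = depth,
       postorder = post, preorder = pre, desc = desc,
       leaf_ids = setNames(which(is_leaf), labels[is_leaf]))
}

map_gene_leaves <- function(G, S, leaf_map) {
  gl <- names(G$leaf_ids)
  miss <- setdiff(gl, names(leaf_map))
  if (length(miss))
    stop("unmapped gene leaf: ", paste(miss, collapse = ", "), call. = FALSE)
  sp <- leaf_map[gl]
  bad <- setdiff(sp, names(S$leaf_ids))
  if (length(bad))
    stop("leaf map targets absent from species tree: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  setNames(S$leaf_ids[sp], G$leaf_ids[gl])  # gene leaf id -> species leaf id
}

#' Reconcile a gene tree with a species tree (DTL parsimony)
#'
#' Computes one minimum-cost reconciliation under the undated DTL model
#' (see the package vignette for the model and tie-breaking rules) and the
#' full event list: speciations, duplications, transfers with
#' donor/recipient species branches, and losses.
#'
#' @param gene_tree,species_tree rooted binary `phylo` objects.
#' @param leaf_map named character vector: gene leaf -> species leaf.
#' @param costs an [event_costs()].
#' @param count_optima also count the number of co-optimal histories.
#' @return a `reconciliation` list: `total_cost`, `events` (data.frame with
#'   `type`, `gene_node`, `species`, `donor`, `recipient`), event counts,
#'   `mapping` (gene node label -> species branch label), and optionally
#'   `n_optima`.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map,
                      costs = event_costs(), count_optima = FALSE) {
  G <- tree_index(gene_tree, "gene tree")
  S <- tree_index(species_tree, "species tree")
  gmap <- map_gene_leaves(G, S, leaf_map)
  nS <- S$n; nG <- G$n
  L <- costs$loss; D <- costs$duplication; Tr <- costs$transfer
  comp <- S$desc | t(S$desc)  # comparable species-node pairs

  C <- matrix(Inf, nG, nS); IN <- matrix(Inf, nG, nS); OUT <- matrix(Inf, nG, nS)
  in_choice <- matrix(0L, nG, nS)    # 0 = resolve here, else chosen child id
  out_arg <- matrix(NA_integer_, nG, nS)
  ev_choice <- matrix(NA_integer_, nG, nS)  # 1 spec a, 2 spec b, 3 dup, 4 tr(u1 stays), 5 tr(u2 stays)
  if (count_optima) {
    CN <- matrix(0, nG, nS); INN <- matrix(0, nG, nS); OUTN <- matrix(0, nG, nS)
  }

  for (u in G$postorder) {
    if (G$is_leaf[u]) {
      C[u, gmap[[as.character(u)]]] <- 0
      if (count_optima) CN[u, gmap[[as.character(u)]]] <- 1
    } else {
      u1 <- G$children[[u]][1L]; u2 <- G$children[[u]][2L]
      for (x in seq_len(nS)) {
        opts <- rep(Inf, 5)
        if (!S$is_leaf[x]) {
          y <- S$children[[x]][1L]; z <- S$children[[x]][2L]
          opts[1] <- IN[u1, y] + IN[u2, z]
          opts[2] <- IN[u1, z] + IN[u2, y]
        }
        opts[3] <- D + IN[u1, x] + IN[u2, x]
        opts[4] <- Tr + IN[u1, x] + OUT[u2, x]
        opts[5] <- Tr + IN[u2, x] + OUT[u1, x]
        best <- min(opts)
        C[u, x] <- best
        # tie preference: speciation > duplication > transfer
        ev_choice[u, x] <- which(opts <= best + COST_TOL)[1L]
        if (count_optima && is.finite(best)) {
          w <- which(opts <= best + COST_TOL)
          cnt <- 0
          for (o in w) {
            cnt <- cnt + switch(o,
              INN[u1, y] * INN[u2, z],
              INN[u1, z] * INN[u2, y],
              INN[u1, x] * INN[u2, x],
              INN[u1, x] * OUTN[u2, x],
              INN[u2, x] * OUTN[u1, x])
          }
          CN[u, x] <- cnt
        }
      }
    }
    # IN: species postorder
    for (x in S$postorder) {
      IN[u, x] <- C[u, x]; in_choice[u, x] <- 0L
      if (count_optima) INN[u, x] <- if (is.finite(C[u, x])) CN[u, x] else 0
      for (k in S$children[[x]]) {
        cand <- L + IN[u, k]
        if (cand < IN[u, x] - COST_TOL) {
          IN[u, x] <- cand; in_choice[u, x] <- k
          if (count_optima) INN[u, x] <- INN[u, k]
        } else if (count_optima && is.finite(cand) &&
                   abs(cand - IN[u, x]) <= COST_TOL) {
          INN[u, x] <- INN[u, x] + INN[u, k]
        }
      }
    }
    # OUT: min over incomparable nodes
    for (x in seq_len(nS)) {
      pool <- which(!comp[x, ])
      if (!length(pool)) next
      vals <- IN[u, pool]
      j <- which.min(vals)  # lowest id among ties (pool is ascending)
      OUT[u, x] <- vals[j]; out_arg[u, x] <- pool[j]
      if (count_optima && is.finite(OUT[u, x]))
        OUTN[u, x] <- sum(INN[u, pool[abs(vals - OUT[u, x]) <= COST_TOL]])
    }
  }

  roots <- C[G$root, ]
  total <- min(roots)
  if (!is.finite(total))
    stop("no finite-cost reconciliation (are transfers disabled on an ",
         "incongruent family?)", call. = FALSE)
  x0 <- which(roots <= total + COST_TOL)[1L]

  # ---- backtrack one optimal history ----
  events <- list()
  mapping <- character(nG)
  add_ev <- function(type, u, x, donor = NA, recipient = NA) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, gene_node = G$labels[u], species = S$labels[x],
      donor = if (is.na(donor)) NA_character_ else S$labels[donor],
      recipient = if (is.na(recipient)) NA_character_ else S$labels[recipient],
      stringsAsFactors = FALSE)
  }
  descend <- function(u, x) {
    while (in_choice[u, x] != 0L) {
      k <- in_choice[u, x]
      sib <- setdiff(S$children[[x]], k)
      add_ev("loss", u, sib)
      x <- k
    }
    walk(u, x)
  }
  walk <- function(u, x) {
    mapping[u] <<- S$labels[x]
    if (G$is_leaf[u]) return(invisible())
    u1 <- G$children[[u]][1L]; u2 <- G$children[[u]][2L]
    ch <- ev_choice[u, x]
    if (ch == 1L || ch == 2L) {
      add_ev("speciation", u, x)
      y <- S$children[[x]][1L]; z <- S$children[[x]][2L]
      if (ch == 1L) { descend(u1, y); descend(u2, z) }
      else { descend(u1, z); descend(u2, y) }
    } else if (ch == 3L) {
      add_ev("duplication", u, x)
      descend(u1, x); descend(u2, x)
    } else {
      stay <- if (ch == 4L) u1 else u2
      move <- if (ch == 4L) u2 else u1
      r <- out_arg[move, x]
      add_ev("transfer", u, x, donor = x, recipient = r)
      descend(stay, x)
      descend(move, r)
    }
  }
  walk(G$root, x0)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), gene_node = character(),
               species = character(), donor = character(),
               recipient = character(), stringsAsFactors = FALSE)
  n_spec <- sum(events$type == "speciation")
  n_dup <- sum(events$type == "duplication")
  n_tr <- sum(events$type == "transfer")
  n_loss <- sum(events$type == "loss")
  check <- L * n_loss + D * n_dup + Tr * n_tr
  if (is.finite(check) && abs(check - total) > 1e-6)
    stop("internal error: backtracked event costs (", check,
         ") disagree with DP total (", total, ")", call. = FALSE)
  res <- list(total_cost = total, events = events,
              n_speciations = n_spec, n_duplications = n_dup,
              n_transfers = n_tr, n_losses = n_loss,
              mapping = setNames(mapping, G$labels),
              costs = costs)
  if (count_optima) res$n_optima <- sum(CN[G$root,
                                           abs(roots - total) <= COST_TOL])
  class(res) <- "reconciliation"
  res
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("DTL reconciliation: cost", format(x$total_cost), "|",
      x$n_speciations, "speciations,", x$n_duplications, "duplications,",
      x$n_transfers, "transfers,", x$n_losses, "losses\n")
  tr <- x$events[x$events$type == "transfer", , drop = FALSE]
  if (nrow(tr))
    cat(paste0("  HGT ", tr$donor, " -> ", tr$recipient, collapse = "\n"), "\n")
  invisible(x)
}

#' Brute-force minimum reconciliation cost (independent oracle)
#'
#' Enumerates every assignment of gene-tree internal nodes to species nodes
#' explicitly and, for each assignment, takes the cheapest event
#' (speciation / duplication / transfer with every possible recipient)
#' independently at each gene node, with losses charged per skipped species
#' branch. Shares no code with the dynamic program in [reconcile()]; only
#' practical for small trees (<= ~6 leaves).
#'
#' @inheritParams reconcile
#' @return the minimum total cost (numeric).
#' @export
reconcile_brute <- function(gene_tree, species_tree, leaf_map,
                            costs = event_costs()) {
  G <- tree_index(gene_tree, "gene tree")
  S <- tree_index(species_tree, "species tree")
  gmap <- map_gene_leaves(G, S, leaf_map)
  nS <- S$n
  L <- costs$loss; D <- costs$duplication; Tr <- costs$transfer
  dist_down <- matrix(Inf, nS, nS)
  for (x in seq_len(nS)) for (y in seq_len(nS))
    if (S$desc[x, y]) dist_down[x, y] <- S$depth[y] - S$depth[x]
  comp <- S$desc | t(S$desc)

  # local event-cost table: cheapest event at species node x for a gene node
  # whose children resolve at species nodes x1 and x2
  local <- array(Inf, dim = c(nS, nS, nS))
  for (x in seq_len(nS)) for (x1 in seq_len(nS)) for (x2 in seq_len(nS)) {
    best <- Inf
    if (!S$is_leaf[x]) {
      y <- S$children[[x]][1L]; z <- S$children[[x]][2L]
      if (S$desc[y, x1] && S$desc[z, x2])
        best <- min(best, L * (dist_down[y, x1] + dist_down[z, x2]))
      if (S$desc[z, x1] && S$desc[y, x2])
        best <- min(best, L * (dist_down[z, x1] + dist_down[y, x2]))
    }
    if (S$desc[x, x1] && S$desc[x, x2])
      best <- min(best, D + L * (dist_down[x, x1] + dist_down[x, x2]))
    for (r in which(!comp[x, ])) {
      if (S$desc[x, x1] && S$desc[r, x2])
        best <- min(best, Tr + L * (dist_down[x, x1] + dist_down[r, x2]))
      if (S$desc[x, x2] && S$desc[r, x1])
        best <- min(best, Tr + L * (dist_down[x, x2] + dist_down[r, x1]))
    }
    local[x, x1, x2] <- best
  }

  internals <- which(!G$is_leaf)
  if (!length(internals)) return(0)
  grids <- rep(list(seq_len(nS)), length(internals))
  m <- as.matrix(do.call(expand.grid, grids))  # rows: candidate mappings
  node_col <- setNames(seq_along(internals), internals)
  total <- numeric(nrow(m))
  for (u in internals) {
    kids <- G$children[[u]]
    xs <- m[, node_col[[as.character(u)]]]
    x1 <- if (G$is_leaf[kids[1L]]) rep(gmap[[as.character(kids[1L])]], nrow(m))
          else m[, node_col[[as.character(kids[1L])]]]
    x2 <- if (G$is_leaf[kids[2L]]) rep(gmap[[as.character(kids[2L])]], nrow(m))
          else m[, node_col[[as.character(kids[2L])]]]
    total <- total + local[cbind(xs, x1, x2)]
  }
  min(total)
}

#' Closed-form duplication-loss cost of the classical LCA mapping
#'
#' Independent of the DP in [reconcile()]: maps every gene node to the LCA
#' of its children's images and applies the textbook duplication/loss
#' counting rules. Equals the DTL minimum when transfers are disabled
#' (`transfer = Inf`).
#'
#' @inheritParams reconcile
#' @return list with `cost`, `n_duplications`, `n_losses`.
#' @export
dl_cost_lca <- function(gene_tree, species_tree, leaf_map,
                        costs = event_costs()) {
  G <- tree_index(gene_tree, "gene tree")
  S <- tree_index(species_tree, "species tree")
  gmap <- map_gene_leaves(G, S, leaf_map)
  lca <- function(x, y) {
    while (x != y) {
      if (S$depth[x] > S$depth[y]) x <- S$parent[x] else y <- S$parent[y]
    }
    x
  }
  M <- integer(G$n)
  for (u in G$postorder) {
    M[u] <- if (G$is_leaf[u]) gmap[[as.character(u)]] else
      lca(M[G$children[[u]][1L]], M[G$children[[u]][2L]])
  }
  ndup <- 0L; nloss <- 0L
  for (u in which(!G$is_leaf)) {
    kids <- G$children[[u]]
    isdup <- any(M[kids] == M[u])
    if (isdup) ndup <- ndup + 1L
    for (v in kids) {
      d <- S$depth[M[v]] - S$depth[M[u]]
      nloss <- nloss + d - (!isdup)  # speciation consumes one level
    }
  }
  list(cost = costs$duplication * ndup + costs$loss * nloss,
       n_duplications = ndup, n_losses = nloss)
}

canonical_newick <- function(phy) {
  T <- tree_index(phy)
  build <- function(v) {
    if (T$is_leaf[v]) return(T$labels[v])
    paste0("(", paste(sort(vapply(T$children[[v]], build, character(1))),
                      collapse = ","), ")")
  }
  paste0(build(T$root), ";")
}

#' Root an unrooted gene tree by reconciliation cost
#'
#' Evaluates [reconcile()] for the rooting on every edge of an unrooted
#' binary gene tree (`2n - 3` rootings) and returns the cheapest; ties are
#' broken by the smallest canonical Newick string of the rooted tree.
#'
#' @param gene_tree unrooted binary `phylo` with >= 3 leaves.
#' @inheritParams reconcile
#' @return list with `tree` (rooted phylo), `result` (the reconciliation),
#'   and `n_rootings` evaluated.
#' @export
root_search <- function(gene_tree, species_tree, leaf_map,
                        costs = event_costs()) {
  if (!inherits(gene_tree, "phylo")) stop("gene_tree must be phylo", call. = FALSE)
  ntip <- length(gene_tree$tip.label)
  if (ntip < 3L) stop("need >= 3 leaves", call. = FALSE)
  if (ape::is.rooted(gene_tree)) gene_tree <- ape::unroot(gene_tree)
  if (!ape::is.binary(gene_tree))
    stop("non-binary: unrooted gene tree must be binary", call. = FALSE)
  tips_below <- function(node) {
    if (node <= ntip) return(gene_tree$tip.label[node])
    unlist(lapply(gene_tree$edge[gene_tree$edge[, 1L] == node, 2L], tips_below))
  }
  best <- NULL
  n_eval <- 0L
  for (i in seq_len(nrow(gene_tree$edge))) {
    og <- tips_below(gene_tree$edge[i, 2L])
    rooted <- ape::root(gene_tree, outgroup = og, resolve.root = TRUE)
    if (!ape::is.binary(rooted) || !ape::is.rooted(rooted)) next
    n_eval <- n_eval + 1L
    res <- reconcile(rooted, species_tree, leaf_map, costs)
    key <- canonical_newick(rooted)
    if (is.null(best) || res$total_cost < best$result$total_cost - COST_TOL ||
        (abs(res$total_cost - best$result$total_cost) <= COST_TOL &&
         key < best$key)) {
      best <- list(tree = rooted, result = res, key = key)
    }
  }
  list(tree = best$tree, result = best$result, n_rootings = n_eval)
}

#' Summarise a reconciliation as a family history verdict
#'
#' `vertical` when there are no transfers; `HGT-dominated` when transfer
#' cost exceeds half the total; otherwise `mixed`.
#'
#' @param result a `reconciliation` from [reconcile()].
#' @return list with event counts, the transfer donor/recipient list, and
#'   `verdict`.
#' @export
classify_family_history <- function(result) {
  stopifnot(inherits(result, "reconciliation"))
  tr <- result$events[result$events$type == "transfer", , drop = FALSE]
  tcost <- result$costs$transfer * result$n_transfers
  verdict <- if (result$n_transfers == 0L) "vertical"
    else if (tcost > 0.5 * result$total_cost) "HGT-dominated"
    else "mixed"
  list(n_speciations = result$n_speciations,
       n_duplications = result$n_duplications,
       n_transfers = result$n_transfers,
       transfers = tr[c("donor", "recipient")],
       n_losses = result$n_losses,
       verdict = verdict)
}
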