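# Generators for every fixture the pipeline needs: annotated genomes with
# planted PULs and enumerated decoys, mutated genome pairs for ANI, and
# gene families evolved top-down along a species tree with recorded
# duplication/transfer/loss events. All generators are pure functions of
# (config, seed).

#' Describe a locus to plant in a synthetic genome
#'
#' @param category PUL rule category: 1 (SusC/D pair + GH-or-PL gene) or
#'   2 (lone SusC + >= 5 GH genes).
#' @param substrate substrate label the locus should classify as.
#' @param families CAZyme families to plant (category 2 needs >= 5 GH
#'   families; repeats allowed and planted as separate genes).
#' @param susCD_gap rank gap between SusC and SusD (category 1 only).
#' @export
planted_locus <- function(category, substrate = "alginate",
                          families = c("PL7", "GH16"), susCD_gap = 1L) {
  stopifnot(category %in% c(1L, 2L), susCD_gap >= 1L)
  if (category == 2L && sum(startsWith(families, "GH")) < 5L)
    stop("category-2 locus needs >= 5 GH families", call. = FALSE)
  list(category = as.integer(category), substrate = substrate,
       families = families, susCD_gap = as.integer(susCD_gap))
}

DECOY_TYPES <- c("pair_too_far", "gh_four", "one_tool_cazyme",
                 "no_cazyme_susC")

#' Genome simulation configuration
#'
#' @param n_genes minimum number of genes (filler genes are appended to
#'   reach it).
#' @param n_replicons number of replicons; planted blocks are distributed
#'   round-robin.
#' @param planted_loci list of [planted_locus()] descriptions.
#' @param decoys character vector drawn from
#'   `c("pair_too_far", "gh_four", "one_tool_cazyme", "no_cazyme_susC")`;
#'   each decoy violates exactly one rule condition.
#' @param n_peptidases,n_sulfatases background genes given MEROPS/SulfAtlas
#'   hits below the calling threshold.
#' @param seed RNG seed.
#' @export
genome_sim_config <- function(n_genes = 120L, n_replicons = 1L,
                              planted_loci = list(), decoys = character(),
                              n_peptidases = 0L, n_sulfatases = 0L,
                              seed = 1L) {
  bad <- setdiff(decoys, DECOY_TYPES)
  if (length(bad)) stop("unknown decoy type: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicons = as.integer(n_replicons),
                 planted_loci = planted_loci, decoys = decoys,
                 n_peptidases = as.integer(n_peptidases),
                 n_sulfatases = as.integer(n_sulfatases),
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

# one planted block = ordered gene specs; buffer filler keeps blocks from
# interacting through the window rules
locus_block <- function(pl) {
  specs <- list(list(role = "susC"))
  if (pl$category == 1L) {
    for (i in seq_len(pl$susCD_gap - 1L)) specs <- c(specs, list(list(role = "filler")))
    specs <- c(specs, list(list(role = "susD")))
  }
  for (f in pl$families) specs <- c(specs, list(list(role = "cazyme", family = f)))
  specs
}

decoy_block <- function(type) {
  switch(type,
    pair_too_far = c(list(list(role = "susC")),
                     rep(list(list(role = "filler")), 3L),
                     list(list(role = "susD"), list(role = "cazyme", family = "GH16"))),
    gh_four = c(list(list(role = "susC")),
                lapply(c("GH3", "GH16", "GH29", "GH43"),
                       function(f) list(role = "cazyme", family = f))),
    one_tool_cazyme = list(list(role = "susC"), list(role = "susD"),
                           list(role = "cazyme1tool", family = "GH16")),
    no_cazyme_susC = list(list(role = "susC")))
}

#' Simulate an annotated genome with planted loci and decoys
#'
#' Produces a gene table with uniform random gene lengths and intergenic
#' gaps, domain-hit tables per source database (planted SusC genes emit
#' TIGR04056 hits, SusD genes PF07980 hits, CAZymes hits from two dbCAN
#' tools so they pass the 2-of-3 consensus; `one_tool_cazyme` decoy CAZymes
#' get a single-tool hit), a random nucleotide sequence, and the planted
#' truth. Deterministic given the config seed. Filler genes carry no hits.
#'
#' @param config a [genome_sim_config()].
#' @return list with `genes` (a `gene_table`), `hits` (named list of
#'   `domain_hits`-shaped data.frames per source db), `seq`
#'   (DNAStringSet), and `truth` (list with `loci` and `decoys`
#'   data.frames; spans are gene ranks).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  buffer <- 12L  # > window (10) so planted blocks cannot interact
  blocks <- c(lapply(config$planted_loci, function(pl)
                list(kind = "locus", pl = pl, specs = locus_block(pl))),
              lapply(config$decoys, function(d)
                list(kind = "decoy", type = d, specs = decoy_block(d))))
  # assign blocks to replicons round-robin
  reps <- paste0("rep", seq_len(config$n_replicons))
  specs_by_rep <- setNames(vector("list", length(reps)), reps)
  block_rep <- if (length(blocks))
    reps[(seq_along(blocks) - 1L) %% length(reps) + 1L] else character(0)
  truth_loci <- list(); truth_decoys <- list()
  gene_counter <- 0L
  genes <- list(); hits <- list()
  filler_spec <- list(role = "filler")
  for (r in reps) {
    specs <- rep(list(filler_spec), buffer)
    marks <- list()
    for (bi in which(block_rep == r)) {
      start_rank <- length(specs)  # 0-based rank of first block gene
      specs <- c(specs, blocks[[bi]]$specs, rep(list(filler_spec), buffer))
      marks[[length(marks) + 1L]] <- list(block = blocks[[bi]],
                                          from = start_rank,
                                          to = start_rank + length(blocks[[bi]]$specs) - 1L)
    }
    specs_by_rep[[r]] <- specs
    for (mk in marks) {
      if (mk$block$kind == "locus") {
        pl <- mk$block$pl
        roles <- vapply(mk$block$specs, `[[`, character(1), "role")
        keep <- roles != "filler"
        truth_loci[[length(truth_loci) + 1L]] <- data.frame(
          replicon_id = r,
          span_min = mk$from + which(keep)[1L] - 1L,
          span_max = mk$from + utils::tail(which(keep), 1L) - 1L,
          rule_category = pl$category, substrate = pl$substrate,
          families = paste(sort(pl$families), collapse = ","),
          stringsAsFactors = FALSE)
      } else {
        truth_decoys[[length(truth_decoys) + 1L]] <- data.frame(
          replicon_id = r, span_min = mk$from, span_max = mk$to,
          type = mk$block$type, stringsAsFactors = FALSE)
      }
    }
  }
  # top up with filler to reach n_genes
  total <- sum(lengths(specs_by_rep))
  if (total < config$n_genes) {
    extra <- config$n_genes - total
    specs_by_rep[[reps[1L]]] <- c(specs_by_rep[[reps[1L]]],
                                  rep(list(filler_spec), extra))
  }
  # background peptidase/sulfatase genes live on trailing filler genes
  gene_rows <- list(); hit_rows <- list()
  for (r in reps) {
    pos <- 1L
    for (spec in specs_by_rep[[r]]) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%04d", gene_counter)
      len <- sample(600:1800, 1L)
      gap <- sample(20:200, 1L)
      start <- pos + gap
      gene_rows[[gene_counter]] <- data.frame(
        gene_id = gid, replicon_id = r, rank = NA_integer_,
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L),
        product = switch(spec$role,
                         susC = "TonB-dependent transporter SusC",
                         susD = "SusD family lipoprotein",
                         cazyme = , cazyme1tool = "glycoside hydrolase",
                         "hypothetical protein"),
        stringsAsFactors = FALSE)
      pos <- start + len
      hit_rows[[gene_counter]] <- switch(spec$role,
        susC = data.frame(gene_id = gid, accession = "TIGR04056",
                          tool = "BLASTP", evalue = 1e-40,
                          source_db = "TIGRFAM", stringsAsFactors = FALSE),
        susD = data.frame(gene_id = gid, accession = "PF07980",
                          tool = "BLASTP", evalue = 1e-30,
                          source_db = "Pfam", stringsAsFactors = FALSE),
        cazyme = data.frame(gene_id = gid, accession = spec$family,
                            tool = c("HMMER", "DIAMOND"),
                            evalue = c(1e-30, 1e-25),
                            source_db = "CAZy", stringsAsFactors = FALSE),
        cazyme1tool = data.frame(gene_id = gid, accession = spec$family,
                                 tool = "HMMER", evalue = 1e-30,
                                 source_db = "CAZy", stringsAsFactors = FALSE),
        NULL)
    }
  }
  genes <- do.call(rbind, gene_rows)
  # peptidase/sulfatase background on the last filler genes (no role overlap)
  filler_ids <- genes$gene_id[!(genes$gene_id %in%
    unlist(lapply(hit_rows, function(h) h$gene_id)))]
  extra_hits <- list()
  nps <- config$n_peptidases + config$n_sulfatases
  if (nps > length(filler_ids))
    stop("not enough filler genes for peptidase/sulfatase background",
         call. = FALSE)
  if (config$n_peptidases > 0L) {
    ids <- utils::tail(filler_ids, nps)[seq_len(config$n_peptidases)]
    extra_hits[[1L]] <- data.frame(gene_id = ids, accession = "M01.001",
                                   tool = "BLASTP", evalue = 1e-30,
                                   source_db = "MEROPS", stringsAsFactors = FALSE)
  }
  if (config$n_sulfatases > 0L) {
    ids <- utils::tail(filler_ids, config$n_sulfatases)
    extra_hits[[2L]] <- data.frame(gene_id = ids, accession = "S1_0",
                                   tool = "BLASTP", evalue = 1e-30,
                                   source_db = "SulfAtlas", stringsAsFactors = FALSE)
  }
  all_hits <- c(hit_rows[!vapply(hit_rows, is.null, logical(1))], extra_hits)
  hits_by_db <- if (length(all_hits)) {
    hits_df <- do.call(rbind, all_hits)
    lapply(split(hits_df, hits_df$source_db), function(h) {
      rownames(h) <- NULL
      class(h) <- c("domain_hits", "data.frame")
      h
    })
  } else list()
  genes <- assign_ranks(genes)
  validate_gene_table(genes)
  # random sequence long enough for every replicon
  seqs <- Biostrings::DNAStringSet(vapply(reps, function(r) {
    len <- max(genes$end[genes$replicon_id == r]) + 100L
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- reps
  truth <- list(
    loci = if (length(truth_loci)) do.call(rbind, truth_loci) else
      data.frame(replicon_id = character(), span_min = integer(),
                 span_max = integer(), rule_category = integer(),
                 substrate = character(), families = character(),
                 stringsAsFactors = FALSE),
    decoys = if (length(truth_decoys)) do.call(rbind, truth_decoys) else
      data.frame(replicon_id = character(), span_min = integer(),
                 span_max = integer(), type = character(),
                 stringsAsFactors = FALSE),
    seed = config$seed)
  list(genes = new_gene_table(genes), hits = hits_by_db, seq = seqs,
       truth = truth)
}

#' Apply uniform point mutations to a genome
#'
#' Each base is independently substituted to a uniformly chosen different
#' base with probability `rate`.
#'
#' @param seq genome sequences.
#' @param rate substitution probability per base, `0 <= rate < 0.25`.
#' @param seed RNG seed.
#' @export
mutate_genome <- function(seq, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 0.25)
  seqs <- as_dss(seq)
  with_seed(seed, {
    out <- vapply(seq_along(seqs), function(i) {
      ch <- strsplit(as.character(seqs[[i]]), "")[[1L]]
      hit <- which(stats::runif(length(ch)) < rate)
      if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        repl <- vapply(ch[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
        ch[hit] <- repl
      }
      paste(ch, collapse = "")
    }, character(1))
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(seqs)
    res
  })
}

#' Gene-family simulation configuration
#'
#' @param species_tree rooted binary `phylo`.
#' @param p_dup,p_transfer,p_loss per-branch per-copy event probabilities
#'   (at most one event is drawn per copy per branch).
#' @param root_copies gene copies at the species root.
#' @param seed RNG seed.
#' @param max_attempts resampling cap when the family goes extinct.
#' @export
family_sim_config <- function(species_tree, p_dup = 0.02, p_transfer = 0.02,
                              p_loss = 0.02, root_copies = 1L, seed = 1L,
                              max_attempts = 100L) {
  stopifnot(p_dup >= 0, p_dup < 1, p_transfer >= 0, p_transfer < 1,
            p_loss >= 0, p_loss < 1, p_dup + p_transfer + p_loss < 1,
            root_copies >= 1)
  structure(list(species_tree = species_tree, p_dup = p_dup,
                 p_transfer = p_transfer, p_loss = p_loss,
                 root_copies = as.integer(root_copies),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "family_sim_config")
}

#' Evolve a gene family along a species tree with D/T/L events
#'
#' Top-down simulation: each gene copy entering a species branch draws at
#' most one event (loss, duplication, or transfer to a uniformly chosen
#' non-comparable branch) with the configured probabilities, then descends
#' through the speciation at the branch's end. Lost lineages are pruned
#' from the emitted gene tree; families with fewer than two surviving
#' leaves are resampled with derived seeds up to `max_attempts`.
#'
#' @param config a [family_sim_config()].
#' @return list with `gene_tree` (rooted binary phylo), `leaf_map` (leaf ->
#'   species), `truth` (data.frame of all generating events with branch
#'   labels matching [reconcile()] output), `seed`, and `attempts`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  S <- tree_index(config$species_tree, "species tree")
  comp <- S$desc | t(S$desc)
  for (attempt in seq_len(config$max_attempts)) {
    sd <- as.integer((as.numeric(config$seed) + 7919 * (attempt - 1)) %%
                       2147483647)
    res <- with_seed(sd, simulate_family_once(config, S, comp))
    if (!is.null(res)) {
      res$seed <- config$seed; res$attempts <- attempt
      return(res)
    }
  }
  stop("family went extinct in every attempt; lower p_loss", call. = FALSE)
}

simulate_family_once <- function(config, S, comp) {
  events <- list()
  leaf_counter <- new.env(parent = emptyenv())
  add_event <- function(type, branch, donor = NA_integer_,
                        recipient = NA_integer_) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, branch = S$labels[branch],
      donor = if (is.na(donor)) NA_character_ else S$labels[donor],
      recipient = if (is.na(recipient)) NA_character_ else S$labels[recipient],
      stringsAsFactors = FALSE)
  }
  new_leaf <- function(x) {
    sp <- S$labels[x]
    k <- (get0(sp, envir = leaf_counter) %||% 0L) + 1L
    assign(sp, k, envir = leaf_counter)
    paste0(sp, "_g", k)
  }
  # a copy resolved at species node x: speciate or emit a leaf
  at_node <- function(x) {
    if (S$is_leaf[x]) return(new_leaf(x))
    kids <- lapply(S$children[[x]], on_branch)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    list(kids[[1L]], kids[[2L]])
  }
  # a copy entering the branch above node x: draw at most one event
  on_branch <- function(x) {
    u <- stats::runif(1L)
    if (u < config$p_loss) {
      add_event("loss", x)
      return(NULL)
    }
    if (u < config$p_loss + config$p_dup) {
      add_event("duplication", x)
      a <- descend_quiet(x); b <- descend_quiet(x)
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      return(list(a, b))
    }
    if (u < config$p_loss + config$p_dup + config$p_transfer) {
      pool <- which(!comp[x, ])
      if (length(pool)) {
        r <- pool[sample.int(length(pool), 1L)]
        add_event("transfer", x, donor = x, recipient = r)
        stay <- at_node(x)
        moved <- on_branch(r)
        if (is.null(stay)) return(moved)
        if (is.null(moved)) return(stay)
        return(list(stay, moved))
      }
    }
    at_node(x)
  }
  # continuation after a duplication: no further events on this branch
  descend_quiet <- function(x) at_node(x)
  root_subtrees <- list()
  for (i in seq_len(config$root_copies)) {
    st <- at_node(S$root)
    if (!is.null(st)) root_subtrees[[length(root_subtrees) + 1L]] <- st
  }
  tree <- if (!length(root_subtrees)) NULL
    else Reduce(function(a, b) list(a, b), root_subtrees)
  nleaves <- function(t) if (is.character(t)) 1L else
    nleaves(t[[1L]]) + nleaves(t[[2L]])
  if (is.null(tree) || nleaves(tree) < 2L) return(NULL)
  to_newick <- function(t) if (is.character(t)) t else
    paste0("(", to_newick(t[[1L]]), ",", to_newick(t[[2L]]), ")")
  gt <- ape::read.tree(text = paste0(to_newick(tree), ";"))
  leaves <- gt$tip.label
  leaf_map <- setNames(sub("_g[0-9]+$", "", leaves), leaves)
  truth <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), branch = character(),
               donor = character(), recipient = character(),
               stringsAsFactors = FALSE)
  list(gene_tree = gt, leaf_map = leaf_map, truth = truth)
}

#' Random rooted binary species tree
#'
#' @param n number of species (tips labelled `sp1..spn`).
#' @param seed RNG seed.
#' @export
random_species_tree <- function(n, seed = 1L) {
  with_seed(seed, ape::rtree(n, tip.label = paste0("sp", seq_len(n))))
}
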