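# Rule-based PUL prediction from the ordered gene table plus per-gene roles.
#
# Two seed rules delimit candidate loci, following common practice for
# Bacteroidota genome mining:
#   (i)  a SusC/D pair with at least one GH or PL gene within `window`
#        genes up- or downstream of the pair;
#   (ii) a lone SusC with >= `min_gh_rule2` GH genes within `window` genes.
# Overlapping seeds on one replicon merge into a single locus. Substrates
# are called from the CAZyme family profile; an alginate utilization locus
# (AUL) additionally requires a SusC/D pair.

#' Default substrate marker families
#'
#' Named list mapping substrate labels to the CAZyme families taken as
#' evidence for them. The alginate set is the 15 polysaccharide lyase
#' families with known alginate lyase activity.
#'
#' @export
default_substrate_map <- function() {
  list(
    alginate = c("PL5", "PL6", "PL7", "PL8", "PL14", "PL15", "PL17", "PL18",
                 "PL31", "PL32", "PL34", "PL36", "PL38", "PL39", "PL41"),
    fucoidan = c("GH29", "GH95"),
    laminarin = c("GH16", "GH17", "GH30"),
    `beta-mannan` = c("GH130", "GH26"),
    xylan = c("GH43", "GH30", "GH10"),
    `alpha-mannan` = "GH92",
    rhamnose = "GH78",
    agar = c("GH117", "GH16", "GH50", "GH86"),
    ulvan = c("PL24", "PL25", "PL40")
  )
}

#' PUL rule configuration
#'
#' @param window gene-rank window ("within 10 genes upstream or downstream",
#'   inclusive of a rank difference of exactly `window`).
#' @param min_gh_rule2 distinct GH genes required by the lone-SusC rule.
#' @param pair_max_gap maximum rank gap between SusC and SusD genes of a
#'   pair (2 allows one intervening gene).
#' @param substrate_map named list substrate -> CAZyme families, see
#'   [default_substrate_map()].
#' @param alginate_pl_families PL families accepted as alginate lyases.
#' @param circular treat each replicon as circular (windows wrap around the
#'   origin). Default `FALSE`; locus spans are always reported linearly.
#' @export
pul_rule_config <- function(window = 10L, min_gh_rule2 = 5L,
                            pair_max_gap = 2L,
                            substrate_map = default_substrate_map(),
                            alginate_pl_families = default_substrate_map()$alginate,
                            circular = FALSE) {
  stopifnot(window >= 1, min_gh_rule2 >= 1, pair_max_gap >= 1)
  sm <- substrate_map
  sm$alginate <- alginate_pl_families
  structure(list(window = as.integer(window),
                 min_gh_rule2 = as.integer(min_gh_rule2),
                 pair_max_gap = as.integer(pair_max_gap),
                 substrate_map = sm,
                 alginate_pl_families = alginate_pl_families,
                 circular = isTRUE(circular)),
            class = "pul_rule_config")
}

# per-gene working frame: gene table columns + role columns, families as a
# list column; genes absent from the role table carry empty roles.
gene_role_frame <- function(genes, roles) {
  validate_gene_table(genes)
  g <- as.data.frame(genes)
  idx <- match(g$gene_id, roles$gene_id)
  g$families <- ifelse(is.na(idx), "", roles$cazyme_families[idx])
  g$is_susC <- !is.na(idx) & roles$is_susC[idx]
  g$is_susD <- !is.na(idx) & roles$is_susD[idx]
  g$fam_list <- strsplit(g$families, ",", fixed = TRUE)
  g$has_gh <- vapply(g$fam_list, function(f) any(startsWith(f, "GH")), logical(1))
  g$has_ghpl <- vapply(g$fam_list,
                       function(f) any(startsWith(f, "GH") | startsWith(f, "PL")),
                       logical(1))
  g$is_cazyme <- nzchar(g$families)
  g
}

#' Find SusC/D pairs
#'
#' Pairs each SusD gene with a SusC gene on the same replicon at rank gap
#' `<= pair_max_gap`. Matching is greedy by increasing gap; at equal gap the
#' downstream partner wins; each gene joins at most one pair.
#'
#' @param genes a `gene_table`.
#' @param roles a merged `gene_roles` table.
#' @param config a [pul_rule_config()].
#' @return data.frame with columns `susC_gene`, `susD_gene`, `replicon_id`,
#'   `susC_rank`, `susD_rank`, `rank_gap`.
#' @export
find_susCD_pairs <- function(genes, roles, config = pul_rule_config()) {
  g <- gene_role_frame(genes, roles)
  empty <- data.frame(susC_gene = character(), susD_gene = character(),
                      replicon_id = character(), susC_rank = integer(),
                      susD_rank = integer(), rank_gap = integer(),
                      stringsAsFactors = FALSE)
  sc <- g[g$is_susC, ]; sd <- g[g$is_susD, ]
  if (nrow(sc) == 0L || nrow(sd) == 0L) return(empty)
  cand <- merge(sc[c("gene_id", "replicon_id", "rank")],
                sd[c("gene_id", "replicon_id", "rank")],
                by = "replicon_id", suffixes = c("_C", "_D"))
  cand$rank_gap <- abs(cand$rank_C - cand$rank_D)
  cand <- cand[cand$rank_gap <= config$pair_max_gap, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # greedy: smallest gap first; ties prefer the downstream partner, then
  # lowest ranks for determinism
  cand <- cand[order(cand$rank_gap, cand$rank_D < cand$rank_C,
                     cand$rank_C, cand$rank_D), ]
  used_c <- character(); used_d <- character(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$gene_id_C[i] %in% used_c || cand$gene_id_D[i] %in% used_d) next
    keep[i] <- TRUE
    used_c <- c(used_c, cand$gene_id_C[i])
    used_d <- c(used_d, cand$gene_id_D[i])
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(susC_gene = cand$gene_id_C, susD_gene = cand$gene_id_D,
                    replicon_id = cand$replicon_id,
                    susC_rank = cand$rank_C, susD_rank = cand$rank_D,
                    rank_gap = cand$rank_gap, stringsAsFactors = FALSE)
  out[order(out$replicon_id, pmin(out$susC_rank, out$susD_rank)), ,
      drop = FALSE]
}

# ranks within `window` of the interval [lo, hi] on a replicon of n genes
window_ranks <- function(lo, hi, window, n, circular) {
  r <- (lo - window):(hi + window)
  if (circular) sort(unique(r %% n)) else r[r >= 0 & r < n]
}

#' Predict PULs
#'
#' Applies the two seed rules (see module header), expands each accepted
#' seed to the minimal rank interval covering the seed genes and all
#' CAZyme/SusC/SusD genes inside its window, and merges overlapping loci on
#' a replicon (union of members; rule category = min).
#'
#' @inheritParams find_susCD_pairs
#' @param pairs output of [find_susCD_pairs()]; recomputed when `NULL`.
#' @return a `pul_set` data.frame, one row per locus, with list columns
#'   `members` (gene ids in rank order) and `pair_list`.
#' @export
predict_puls <- function(genes, roles, pairs = NULL,
                         config = pul_rule_config()) {
  if (is.null(pairs)) pairs <- find_susCD_pairs(genes, roles, config)
  seeds <- pul_seeds(genes, roles, pairs, config)
  puls <- merge_seeds(seeds, pairs)
  attr(puls, "config") <- config
  puls
}

# accepted rule seeds before locus merging (one per firing rule application)
pul_seeds <- function(genes, roles, pairs, config) {
  g <- gene_role_frame(genes, roles)
  seeds <- list()
  for (rep in unique(g$replicon_id)) {
    gr <- g[g$replicon_id == rep, ]
    gr <- gr[order(gr$rank), ]
    n <- nrow(gr)
    pr <- pairs[pairs$replicon_id == rep, , drop = FALSE]
    # category 1: SusC/D pair with a GH-or-PL gene in the window of either
    # pair gene
    for (i in seq_len(nrow(pr))) {
      lo <- min(pr$susC_rank[i], pr$susD_rank[i])
      hi <- max(pr$susC_rank[i], pr$susD_rank[i])
      win <- window_ranks(lo, hi, config$window, n, config$circular)
      wg <- gr[gr$rank %in% win, ]
      if (!any(wg$has_ghpl)) next
      seeds[[length(seeds) + 1L]] <-
        make_seed(wg, seed_ranks = lo:hi, category = 1L, replicon = rep)
    }
    # category 2: lone (unpaired) SusC with >= min_gh_rule2 GH genes in
    # window
    paired_c <- pr$susC_gene
    lone <- gr[gr$is_susC & !(gr$gene_id %in% paired_c), ]
    for (i in seq_len(nrow(lone))) {
      r0 <- lone$rank[i]
      win <- window_ranks(r0, r0, config$window, n, config$circular)
      wg <- gr[gr$rank %in% win, ]
      if (sum(wg$has_gh) < config$min_gh_rule2) next
      seeds[[length(seeds) + 1L]] <-
        make_seed(wg, seed_ranks = r0, category = 2L, replicon = rep)
    }
  }
  seeds
}

make_seed <- function(wg, seed_ranks, category, replicon) {
  keep <- wg$is_cazyme | wg$is_susC | wg$is_susD | wg$rank %in% seed_ranks
  mg <- wg[keep, ]
  list(replicon = replicon, span = range(c(mg$rank, seed_ranks)),
       category = category,
       members = mg$gene_id[order(mg$rank)],
       member_ranks = sort(mg$rank),
       families = sort(unlist(mg$fam_list)))
}

merge_seeds <- function(seeds, pairs) {
  empty <- data.frame(pul_id = character(), replicon_id = character(),
                      span_min = integer(), span_max = integer(),
                      rule_category = integer(), n_pairs = integer(),
                      families = character(), stringsAsFactors = FALSE)
  empty$members <- list(); empty$pair_list <- list()
  class(empty) <- c("pul_set", "data.frame")
  if (!length(seeds)) return(empty)
  # merge overlapping spans per replicon until stable
  repeat {
    merged_any <- FALSE
    out <- list()
    for (s in seeds) {
      hit <- NULL
      for (j in seq_along(out)) {
        o <- out[[j]]
        if (o$replicon == s$replicon &&
            s$span[1] <= o$span[2] && o$span[1] <= s$span[2]) { hit <- j; break }
      }
      if (is.null(hit)) out[[length(out) + 1L]] <- s
      else {
        o <- out[[hit]]
        o$span <- range(c(o$span, s$span))
        ranks <- c(o$member_ranks, s$member_ranks)
        ids <- c(o$members, s$members)
        keep <- !duplicated(ids)
        ord <- order(ranks[keep])
        o$members <- ids[keep][ord]; o$member_ranks <- ranks[keep][ord]
        o$category <- min(o$category, s$category)
        o$families <- sort(c(o$families, setdiff(s$families, character(0))))
        o$families <- sort(unlist(list(o$families)))
        out[[hit]] <- o
        merged_any <- TRUE
      }
    }
    seeds <- out
    if (!merged_any) break
  }
  ord <- order(vapply(seeds, function(s) s$replicon, character(1)),
               vapply(seeds, function(s) s$span[1], numeric(1)))
  seeds <- seeds[ord]
  rows <- lapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    pl <- pairs[pairs$replicon_id == s$replicon &
                  pairs$susC_rank >= s$span[1] & pairs$susC_rank <= s$span[2] &
                  pairs$susD_rank >= s$span[1] & pairs$susD_rank <= s$span[2], ,
                drop = FALSE]
    df <- data.frame(pul_id = sprintf("PUL%03d", i), replicon_id = s$replicon,
                     span_min = s$span[1], span_max = s$span[2],
                     rule_category = s$category, n_pairs = nrow(pl),
                     families = paste(s$families, collapse = ","),
                     stringsAsFactors = FALSE)
    df$members <- list(s$members)
    df$pair_list <- list(pl)
    df
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("pul_set", "data.frame")
  res
}

#' Classify PUL substrates
#'
#' Substrates are the union of map labels over the locus's CAZyme families.
#' A locus is an AUL iff its substrates include alginate and it contains at
#' least one SusC/D pair. Families with no substrate label are ignored; set
#' `warn_unknown = TRUE` to be told about them.
#'
#' @param puls a `pul_set` from [predict_puls()].
#' @param config a [pul_rule_config()].
#' @param warn_unknown warn about families absent from the substrate map.
#' @return `puls` with `substrates` and `is_AUL` columns filled.
#' @export
classify_substrates <- function(puls, config = pul_rule_config(),
                                warn_unknown = FALSE) {
  fam2sub <- invert_substrate_map(config$substrate_map)
  unknown <- character(0)
  subs <- character(nrow(puls)); aul <- logical(nrow(puls))
  for (i in seq_len(nrow(puls))) {
    fams <- unique(strsplit(puls$families[i], ",", fixed = TRUE)[[1]])
    fams <- fams[nzchar(fams)]
    labs <- sort(unique(unlist(fam2sub[fams])))
    unknown <- c(unknown, setdiff(fams, names(fam2sub)))
    subs[i] <- paste(labs, collapse = ",")
    aul[i] <- "alginate" %in% labs && puls$n_pairs[i] >= 1L
  }
  if (warn_unknown && length(unknown))
    warning("families without substrate label ignored: ",
            paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
  puls$substrates <- subs
  puls$is_AUL <- aul
  puls
}

invert_substrate_map <- function(map) {
  fams <- unique(unlist(map))
  setNames(lapply(fams, function(f)
    names(map)[vapply(map, function(v) f %in% v, logical(1))]), fams)
}

#' Per-genome PUL counts by substrate
#'
#' @param pul_list named list: genome id -> classified `pul_set`. Genomes
#'   with zero loci get an all-zero row.
#' @param config a [pul_rule_config()] (defines the substrate columns).
#' @return data.frame: one row per genome with `n_puls`, `n_aul` and one
#'   count column per substrate.
#' @export
summarize_puls <- function(pul_list, config = pul_rule_config()) {
  stopifnot(is.list(pul_list), !is.null(names(pul_list)))
  subs <- names(config$substrate_map)
  rows <- lapply(names(pul_list), function(gid) {
    p <- pul_list[[gid]]
    counts <- setNames(integer(length(subs)), subs)
    n_aul <- 0L; n <- 0L
    if (!is.null(p) && nrow(p) > 0L) {
      if (is.null(p$substrates))
        stop("pul_set for ", gid, " is not classified", call. = FALSE)
      n <- nrow(p)
      n_aul <- sum(p$is_AUL)
      for (s in subs)
        counts[s] <- sum(vapply(strsplit(p$substrates, ",", fixed = TRUE),
                                function(x) s %in% x, logical(1)))
    }
    cbind(data.frame(genome_id = gid, n_puls = n, n_aul = n_aul,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a PUL table to TSV
#'
#' @param puls classified `pul_set`.
#' @param path output TSV.
#' @export
write_pul_table <- function(puls, path) {
  df <- as.data.frame(puls)
  df$members <- vapply(df$members, paste, character(1), collapse = ",")
  df$pair_list <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
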