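test_that("SusC/D pairing: gap limit and downstream tie-break", {
  g <- make_genes(30)
  # adjacent pair
  p <- find_susCD_pairs(g, make_roles(g, susC = 10, susD = 11))
  expect_equal(nrow(p), 1L)
  expect_equal(p$rank_gap, 1L)
  # gap 4 > pair_max_gap 2: no pair
  expect_equal(nrow(find_susCD_pairs(g, make_roles(g, susC = 10, susD = 14))),
               0L)
  # SusD at 9 and 11: downstream partner wins the tie
  p <- find_susCD_pairs(g, make_roles(g, susC = 10, susD = c(9, 11)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$susD_rank, 11L)
  # pairs never straddle replicons
  g2 <- rbind(make_genes(5, "r1", "a"), make_genes(5, "r2", "b"))
  g2$rank <- c(0:4, 0:4)
  class(g2) <- c("gene_table", "data.frame")
  roles <- make_roles(g2, susC = integer(0))
  roles <- rbind(
    make_roles(g2[g2$replicon_id == "r1", ], susC = 4),
    make_roles(g2[g2$replicon_id == "r2", ], susD = 0))
  expect_equal(nrow(find_susCD_pairs(g2, roles)), 0L)
})

test_that("rule seeds follow the two categories and the 10-gene window", {
  g <- make_genes(60)
  # category 1: pair at (10,11), GH16 at 15
  puls <- predict_puls(g, make_roles(g, susC = 10, susD = 11,
                                     cazyme = list(`15` = "GH16")))
  expect_equal(nrow(puls), 1L)
  expect_equal(puls$rule_category, 1L)
  expect_equal(c(puls$span_min, puls$span_max), c(10L, 15L))
  expect_equal(puls$n_pairs, 1L)
  # category 2: lone SusC at 20, five GH genes at 22..26
  caz <- setNames(as.list(rep("GH3", 5L)), as.character(22:26))
  puls <- predict_puls(g, make_roles(g, susC = 20, cazyme = caz))
  expect_equal(puls$rule_category, 2L)
  expect_equal(c(puls$span_min, puls$span_max), c(20L, 26L))
  # 4 GH genes fail rule (ii)
  caz4 <- setNames(as.list(rep("GH3", 4L)), as.character(22:25))
  expect_equal(nrow(predict_puls(g, make_roles(g, susC = 20, cazyme = caz4))),
               0L)
  # nearest GH/PL outside window 10
  expect_equal(nrow(predict_puls(g, make_roles(g, susC = 10, susD = 11,
                                               cazyme = list(`22` = "GH16")))),
               0L)
  # exactly at the window boundary (rank difference 10): included
  expect_equal(nrow(predict_puls(g, make_roles(g, susC = 10, susD = 11,
                                               cazyme = list(`21` = "GH16")))),
               1L)
  # a GT-only gene does not satisfy the GH-or-PL requirement
  expect_equal(nrow(predict_puls(g, make_roles(g, susC = 10, susD = 11,
                                               cazyme = list(`12` = "GT2")))),
               0L)
})

test_that("overlapping seeds merge into one locus; spans never overlap", {
  g <- make_genes(60)
  roles <- make_roles(g, susC = c(10, 16), susD = c(11, 17),
                      cazyme = list(`13` = "PL7", `14` = "GH16",
                                    `15` = "GH3"))
  puls <- predict_puls(g, roles)
  expect_equal(nrow(puls), 1L)
  expect_equal(puls$n_pairs, 2L)
  # general non-overlap invariant on synthetic cohorts
  for (seed in 1:6) {
    sim <- simulate_genome(genome_sim_config(
      n_genes = 150,
      planted_loci = list(planted_locus(1), planted_locus(2,
        substrate = "laminarin",
        families = c("GH16", "GH17", "GH30", "GH3", "GH5"))),
      decoys = c("pair_too_far", "gh_four"), seed = seed))
    roles <- pulrecon:::annotate_genome(sim$hits, marker_config())
    puls <- predict_puls(sim$genes, roles)
    for (rep in unique(puls$replicon_id)) {
      p <- puls[puls$replicon_id == rep, ]
      if (nrow(p) > 1L) {
        p <- p[order(p$span_min), ]
        expect_true(all(p$span_min[-1L] > p$span_max[-nrow(p)]))
      }
    }
  }
})

test_that("widening the window never loses rule seeds", {
  for (seed in 1:5) {
    sim <- simulate_genome(genome_sim_config(
      n_genes = 120, planted_loci = list(planted_locus(1)),
      decoys = c("gh_four", "no_cazyme_susC"), seed = seed))
    roles <- pulrecon:::annotate_genome(sim$hits, marker_config())
    n_seeds <- function(w) {
      cfg <- pul_rule_config(window = w)
      pairs <- find_susCD_pairs(sim$genes, roles, cfg)
      length(pulrecon:::pul_seeds(sim$genes, roles, pairs, cfg))
    }
    counts <- vapply(c(2L, 5L, 10L, 20L), n_seeds, integer(1))
    expect_true(all(diff(counts) >= 0L))
  }
})

test_that("substrate classification and the AUL definition", {
  g <- make_genes(40)
  # PL7 + pair: alginate AUL
  puls <- classify_substrates(predict_puls(
    g, make_roles(g, susC = 10, susD = 11, cazyme = list(`12` = "PL7"))))
  expect_match(puls$substrates, "alginate")
  expect_true(puls$is_AUL)
  # PL17 + lone SusC (category 2, needs GH backup): alginate label, no AUL
  caz <- c(list(`12` = "PL17"), setNames(as.list(rep("GH3", 5L)),
                                         as.character(13:17)))
  puls <- classify_substrates(predict_puls(g, make_roles(g, susC = 10,
                                                         cazyme = caz)))
  expect_equal(puls$rule_category, 2L)
  expect_match(puls$substrates, "alginate")
  expect_false(puls$is_AUL)   # no SusC/D pair
  # GH29 marks fucoidan
  puls <- classify_substrates(predict_puls(
    g, make_roles(g, susC = 10, susD = 11, cazyme = list(`12` = "GH29"))))
  expect_match(puls$substrates, "fucoidan")
  # unknown families are ignored (warning only on request)
  puls2 <- predict_puls(g, make_roles(g, susC = 10, susD = 11,
                                      cazyme = list(`12` = "PL7",
                                                    `13` = "GT2")))
  expect_warning(classify_substrates(puls2, warn_unknown = TRUE), "GT2")
})

test_that("every AUL has a pair and an alginate lyase family", {
  cfg <- pul_rule_config()
  for (seed in 1:8) {
    sim <- simulate_genome(genome_sim_config(
      n_genes = 140,
      planted_loci = list(planted_locus(1, families = c("PL17", "GH16")),
                          planted_locus(1, substrate = "fucoidan",
                                        families = "GH29")),
      seed = seed))
    roles <- pulrecon:::annotate_genome(sim$hits, marker_config())
    puls <- classify_substrates(predict_puls(sim$genes, roles, config = cfg),
                                cfg)
    for (i in which(puls$is_AUL)) {
      expect_gte(puls$n_pairs[i], 1L)
      fams <- strsplit(puls$families[i], ",")[[1L]]
      expect_true(any(fams %in% cfg$alginate_pl_families))
    }
  }
})

test_that("per-genome substrate summary counts and zero rows", {
  g <- make_genes(80)
  roles <- make_roles(g, susC = c(10, 40), susD = c(11, 41),
                      cazyme = list(`12` = "PL7", `42` = "PL17",
                                    `60` = "GH29"))
  pairsless <- make_roles(g, susC = 70, susD = 71,
                          cazyme = list(`72` = "GH29"))
  pA <- classify_substrates(predict_puls(g, roles))
  pB <- classify_substrates(predict_puls(g, pairsless))
  sumry <- summarize_puls(list(gA = pA, gB = pB, gEmpty = NULL))
  expect_equal(sumry$n_aul, c(2L, 0L, 0L))
  expect_equal(sumry$alginate, c(2L, 0L, 0L))
  expect_equal(sumry$fucoidan, c(0L, 1L, 0L))
  expect_equal(sumry$n_puls[sumry$genome_id == "gEmpty"], 0L)
})

test_that("circular windows reach across the origin", {
  g <- make_genes(30)
  roles <- make_roles(g, susC = 1, susD = 2, cazyme = list(`28` = "PL7"))
  lin <- predict_puls(g, roles, config = pul_rule_config())
  circ <- predict_puls(g, roles, config = pul_rule_config(circular = TRUE))
  expect_equal(nrow(lin), 0L)   # rank distance 26 linearly
  expect_equal(nrow(circ), 1L)  # 4 genes across the origin
})
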