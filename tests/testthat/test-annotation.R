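test_that("2-of-3 consensus voting with subfamily stripping", {
  hits <- hits_df(
    gene_id = c("g1", "g1", "g1", "g2", "g3", "g3"),
    accession = c("GH16", "GH16", "GH13", "GH5", "GH16_3", "GH16_21"),
    tool = c("HMMER", "DIAMOND", "eCAMI", "HMMER", "HMMER", "eCAMI"),
    evalue = 1e-30, source_db = "CAZy")
  roles <- consensus_cazymes(hits)
  expect_equal(roles$cazyme_families[roles$gene_id == "g1"], "GH16")
  expect_false("g2" %in% roles$gene_id)           # one vote < 2
  expect_equal(roles$cazyme_families[roles$gene_id == "g3"], "GH16")
})

test_that("one vote per (gene, tool): best e-value, ties by accession", {
  hits <- hits_df(
    gene_id = "g1",
    accession = c("GH5", "GH16", "GH16"),
    tool = c("HMMER", "HMMER", "DIAMOND"),
    evalue = c(1e-40, 1e-20, 1e-30), source_db = "CAZy")
  # HMMER's single vote goes to GH5 (better e-value), so GH16 has 1 vote
  expect_equal(nrow(consensus_cazymes(hits)), 0L)
  tie <- hits_df("g1", c("GH16", "GH5", "GH16"),
                 c("HMMER", "HMMER", "DIAMOND"),
                 c(1e-30, 1e-30, 1e-30), "CAZy")
  # equal e-values: lexicographically first accession (GH16 < GH5) wins
  expect_equal(consensus_cazymes(tie)$cazyme_families, "GH16")
})

test_that("multi-family genes keep every family reaching the vote", {
  # each tool casts one vote (its best hit), so with the 2-of-3 default a
  # gene resolves to the majority family; at min_tools = 1 every voted
  # family is kept
  hits <- hits_df(
    gene_id = rep("g1", 3L),
    accession = c("GH16", "GH16", "CBM32"),
    tool = c("HMMER", "DIAMOND", "eCAMI"),
    evalue = 1e-30, source_db = "CAZy")
  expect_equal(consensus_cazymes(hits)$cazyme_families, "GH16")
  expect_equal(
    consensus_cazymes(hits, marker_config(consensus_min_tools = 1))$cazyme_families,
    "CBM32,GH16")
})

test_that("SusC/SusD marker calls respect accession sets and e-cutoff", {
  hits <- hits_df(
    gene_id = c("g4", "g5", "g6"),
    accession = c("TIGR04056", "PF12741", "PF07980"),
    tool = "BLASTP", evalue = c(1e-40, 1e-20, 1e-10),
    source_db = c("TIGRFAM", "Pfam", "Pfam"))
  roles <- call_susCD(hits)
  expect_true(roles$is_susC[roles$gene_id == "g4"])
  expect_true(roles$is_susD[roles$gene_id == "g5"])
  expect_false("g6" %in% roles$gene_id)  # 1e-10 fails e < 1e-15
})

test_that("a gene with SusC and SusD markers is SusC with a warning", {
  hits <- hits_df(rep("g7", 2L), c("TIGR04056", "PF07980"), "BLASTP",
                  1e-40, c("TIGRFAM", "Pfam"))
  expect_warning(roles <- call_susCD(hits), "SusC")
  expect_true(roles$is_susC)
  expect_false(roles$is_susD)
})

test_that("peptidase/sulfatase cutoff is strictly e < 1e-15", {
  hits <- hits_df(c("p1", "p2", "s1"), c("M1", "M2", "S1"), "BLASTP",
                  c(1e-16, 1e-15, 1e-30),
                  c("MEROPS", "MEROPS", "SulfAtlas"))
  roles <- call_peptidases_sulfatases(hits)
  expect_true(roles$is_peptidase[roles$gene_id == "p1"])
  expect_false("p2" %in% roles$gene_id)  # boundary value excluded
  expect_true(roles$is_sulfatase[roles$gene_id == "s1"])
  expect_equal(nrow(call_peptidases_sulfatases(hits[0, ])), 0L)
})

test_that("merge_roles unions roles and keeps them independent", {
  caz <- consensus_cazymes(hits_df(rep("a", 2L), "PL7",
                                   c("HMMER", "DIAMOND"), 1e-30, "CAZy"))
  sus <- call_susCD(hits_df("b", "TIGR04056", "BLASTP", 1e-40, "TIGRFAM"))
  pep <- call_peptidases_sulfatases(hits_df("a", "S1", "BLASTP", 1e-20,
                                            "SulfAtlas"))
  merged <- merge_roles(caz, sus, pep)
  expect_equal(merged$gene_id, c("a", "b"))
  expect_equal(merged$cazyme_families, c("PL7", ""))
  expect_true(merged$is_sulfatase[1L])   # CAZyme + sulfatase both kept
  expect_true(merged$is_susC[2L])
})

test_that("lowering the e-value cutoff never adds a call", {
  set.seed(42)
  hits <- hits_df(paste0("g", 1:50),
                  sample(c("TIGR04056", "PF07980", "PF12741"), 50, TRUE),
                  "BLASTP", 10^-stats::runif(50, 5, 40),
                  sample(c("TIGRFAM", "Pfam"), 50, TRUE))
  loose <- call_susCD(hits, marker_config(evalue_cutoff = 1e-15))
  strict <- call_susCD(hits, marker_config(evalue_cutoff = 1e-25))
  expect_true(all(strict$gene_id %in% loose$gene_id))
  mer <- hits_df(paste0("g", 1:50), "M1", "BLASTP",
                 10^-stats::runif(50, 5, 40), "MEROPS")
  expect_true(all(
    call_peptidases_sulfatases(mer, marker_config(evalue_cutoff = 1e-25))$gene_id
    %in%
    call_peptidases_sulfatases(mer, marker_config(evalue_cutoff = 1e-15))$gene_id))
})

test_that("3-of-3 consensus calls are a subset of 2-of-3 calls", {
  set.seed(7)
  hits <- hits_df(
    rep(paste0("g", 1:30), each = 3L),
    sample(c("GH16", "GH16_3", "GH5", "PL7"), 90, TRUE),
    rep(c("HMMER", "DIAMOND", "eCAMI"), 30),
    1e-30, "CAZy")
  two <- consensus_cazymes(hits, marker_config(consensus_min_tools = 2))
  three <- consensus_cazymes(hits, marker_config(consensus_min_tools = 3))
  expect_lte(nrow(three), nrow(two))
  expect_gt(nrow(two), 0L)
  for (i in seq_len(nrow(three))) {
    g <- three$gene_id[i]
    expect_true(g %in% two$gene_id)
    f3 <- strsplit(three$cazyme_families[i], ",")[[1L]]
    f2 <- strsplit(two$cazyme_families[two$gene_id == g], ",")[[1L]]
    expect_true(all(f3 %in% f2))
  }
})

test_that("identical inputs give identical role tables", {
  sim <- simulate_genome(genome_sim_config(
    planted_loci = list(planted_locus(1)), decoys = "gh_four", seed = 5))
  r1 <- pulrecon:::annotate_genome(sim$hits, marker_config())
  r2 <- pulrecon:::annotate_genome(sim$hits, marker_config())
  expect_identical(r1, r2)
})
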