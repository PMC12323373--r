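# Shared in-code fixture builders. Everything is generated at test time;
# nothing binary ships with the package.

# gene table with n genes on one replicon, ranks 0..n-1
make_genes <- function(n, replicon = "chr", prefix = "g") {
  starts <- seq(1L, by = 1500L, length.out = n)
  df <- data.frame(
    gene_id = sprintf("%s%03d", prefix, seq_len(n)),
    replicon_id = replicon, rank = seq_len(n) - 1L,
    start = starts, end = starts + 999L, strand = "+",
    product = NA_character_, stringsAsFactors = FALSE)
  class(df) <- c("gene_table", "data.frame")
  df
}

# role table builder: susC/susD/cazyme flags by rank (0-based) on make_genes
make_roles <- function(genes, susC = integer(0), susD = integer(0),
                       cazyme = list()) {
  rows <- list()
  add <- function(gid, fam = "", sc = FALSE, sd = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, cazyme_families = fam, is_susC = sc, is_susD = sd,
      is_peptidase = FALSE, is_sulfatase = FALSE, stringsAsFactors = FALSE)
  }
  for (r in susC) add(genes$gene_id[genes$rank == r], sc = TRUE)
  for (r in susD) add(genes$gene_id[genes$rank == r], sd = TRUE)
  for (r in names(cazyme))
    add(genes$gene_id[genes$rank == as.integer(r)],
        fam = paste(cazyme[[r]], collapse = ","))
  if (!length(rows))
    rows <- list(data.frame(gene_id = character(), cazyme_families = character(),
                            is_susC = logical(), is_susD = logical(),
                            is_peptidase = logical(), is_sulfatase = logical(),
                            stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_roles", "data.frame")
  df
}

hits_df <- function(gene_id, accession, tool, evalue, source_db) {
  df <- data.frame(gene_id = gene_id, accession = accession, tool = tool,
                   evalue = evalue, source_db = source_db,
                   stringsAsFactors = FALSE)
  class(df) <- c("domain_hits", "data.frame")
  df
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random reconciliation instance: species tree with k tips, gene tree with
# m leaves labelled by species sampled with repetition
random_recon_instance <- function(k, m, seed) {
  set.seed(seed)
  st <- ape::rtree(k, tip.label = paste0("S", seq_len(k)))
  gt <- ape::rtree(m, tip.label = paste0("L", seq_len(m)))
  map <- stats::setNames(sample(st$tip.label, m, replace = TRUE), gt$tip.label)
  list(species = st, gene = gt, map = map)
}

# all rooted binary gene-tree topologies over a fixed leaf-label vector,
# as Newick strings (used by the exhaustive reconciliation oracle checks)
all_topologies <- function(labels) {
  if (length(labels) == 1L) return(labels)
  out <- character(0)
  n <- length(labels)
  # split: first label stays on the left to avoid mirror duplicates
  others <- labels[-1L]
  for (size in seq_len(n - 1L)) {
    combs <- if (size == 1L) list(character(0))
      else utils::combn(others, size - 1L, simplify = FALSE)
    for (cmb in combs) {
      left <- c(labels[1L], cmb)
      right <- setdiff(labels, left)
      if (!length(right)) next
      for (l in all_topologies(left))
        for (r in all_topologies(right))
          out <- c(out, paste0("(", l, ",", r, ")"))
    }
  }
  out
}
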