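# Readers/writers for the external formats the pipeline touches. All
# downstream modules consume the data.frames produced here, never raw files.

VALID_TOOLS <- c("HMMER", "DIAMOND", "eCAMI", "BLASTP")
VALID_SOURCE_DBS <- c("CAZy", "Pfam", "TIGRFAM", "MEROPS", "SulfAtlas")
# tools accepted per source database: dbCAN3 runs HMMER/DIAMOND/eCAMI against
# CAZy; Pfam/TIGRFAM models are searched with BLASTP or HMMER; MEROPS and
# SulfAtlas hits come from BLASTP only.
TOOLS_BY_DB <- list(
  CAZy     = c("HMMER", "DIAMOND", "eCAMI"),
  Pfam     = c("BLASTP", "HMMER"),
  TIGRFAM  = c("BLASTP", "HMMER"),
  MEROPS   = "BLASTP",
  SulfAtlas = "BLASTP"
)

new_gene_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

# Sort by (replicon, start, end, gene_id) and assign 0-based ranks that
# restart on every replicon. This is the single definition of gene order
# used by the window rules downstream.
assign_ranks <- function(df) {
  ord <- order(df$replicon_id, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$replicon_id)[unique(df$replicon_id)],
                           function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(df) <- NULL
  df
}

validate_gene_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene_id", "replicon_id", "rank", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  if (any(df$start > df$end))
    stop("start > end for gene(s): ",
         paste(df$gene_id[df$start > df$end], collapse = ", "), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  for (rep in split(df$rank, df$replicon_id)) {
    if (!identical(sort(rep), seq_along(rep) - 1L))
      stop("ranks within a replicon must be consecutive 0..n-1", call. = FALSE)
  }
  invisible(df)
}

#' Read a per-genome gene feature table
#'
#' Parses gene order/coordinates/strand from GFF3 (CDS features only), a
#' GenBank flat file (CDS features carrying a `locus_tag`), or a plain TSV
#' with columns `gene_id`, `replicon_id`, `start`, `end`, `strand` and
#' optionally `product`. Features are sorted by `(replicon_id, start, end,
#' gene_id)` and given 0-based ranks restarting on each replicon;
#' coordinates are 1-based inclusive.
#'
#' @param path path to the input file.
#' @param format one of `"gff3"`, `"genbank_ft"`, `"tsv"`.
#' @return a `gene_table` data.frame with columns `gene_id`, `replicon_id`,
#'   `rank`, `start`, `end`, `strand`, `product`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tx\tCDS\t10\t900\t.\t+\t0\tID=g1",
#'   "chr1\tx\tCDS\t1000\t1900\t.\t-\t0\tID=g2"), gff)
#' read_gene_table(gff, "gff3")
#' @export
read_gene_table <- function(path, format = c("gff3", "genbank_ft", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- switch(format,
    gff3       = parse_gff3(path),
    genbank_ft = parse_genbank(path),
    tsv        = parse_gene_tsv(path)
  )
  if (nrow(df) == 0L) stop("no gene features found in ", path, call. = FALSE)
  df <- assign_ranks(df)
  validate_gene_table(df)
  new_gene_table(df)
}

# Minimal GFF3 CDS reader. Purpose-written (rather than rtracklayer) so the
# error contract can name offending line numbers and reject end < start.
parse_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_gene_df())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GFF3 line ", idx[which(nf != 9L)[1L]],
         ": expected 9 tab-separated columns", call. = FALSE)
  m <- do.call(rbind, fields)
  is_cds <- m[, 3L] == "CDS"
  if (!any(is_cds)) return(empty_gene_df())
  m <- m[is_cds, , drop = FALSE]
  lineno <- idx[is_cds]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1L]], ": non-integer coordinates",
         call. = FALSE)
  bad <- which(end < start)
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1L]], ": end < start", call. = FALSE)
  attr_field <- m[, 9L]
  ids <- gff3_attr(attr_field, "ID")
  lt <- gff3_attr(attr_field, "locus_tag")
  ids[is.na(ids)] <- lt[is.na(ids)]
  bad <- which(is.na(ids))
  if (length(bad))
    stop("malformed GFF3 line ", lineno[bad[1L]],
         ": CDS without ID or locus_tag attribute", call. = FALSE)
  data.frame(
    gene_id = ids, replicon_id = m[, 1L], rank = NA_integer_,
    start = start, end = end, strand = m[, 7L],
    product = gff3_attr(attr_field, "product"),
    stringsAsFactors = FALSE
  )
}

gff3_attr <- function(x, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(x, regexec(pat, x))
  vapply(m, function(g) if (length(g) >= 3L) utils::URLdecode(g[3L]) else NA_character_,
         character(1))
}

empty_gene_df <- function() {
  data.frame(gene_id = character(), replicon_id = character(),
             rank = integer(), start = integer(), end = integer(),
             strand = character(), product = character(),
             stringsAsFactors = FALSE)
}

# GenBank flat-file reader: only CDS features with a locus_tag become gene
# features; the locus_tag is the gene_id. Handles `123..456`,
# `complement(123..456)` and partial markers (<, >); join() spans collapse
# to their outer coordinates.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  replicon <- NA_character_
  in_features <- FALSE
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^LOCUS\\s+", ln)) {
      replicon <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
      in_features <- FALSE
    } else if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
    } else if (grepl("^ORIGIN", ln) || grepl("^//", ln)) {
      in_features <- FALSE
    } else if (in_features && grepl("^ {5}CDS\\s+", ln)) {
      loc <- trimws(sub("^ {5}CDS\\s+", "", ln))
      # location may continue on following lines
      while (i < n && grepl("^ {21}[^/]", lines[i + 1L]) &&
             !grepl("^ {21}/", lines[i + 1L])) {
        i <- i + 1L
        loc <- paste0(loc, trimws(lines[i]))
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- suppressWarnings(as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc)))))
      if (length(nums) < 1L || anyNA(nums))
        stop("unparseable CDS location at line ", i, ": ", loc, call. = FALSE)
      locus_tag <- NA_character_; product <- NA_character_
      while (i < n && grepl("^ {21}", lines[i + 1L])) {
        i <- i + 1L
        q <- trimws(lines[i])
        if (grepl("^/locus_tag=", q))
          locus_tag <- gsub('"', "", sub("^/locus_tag=", "", q))
        if (grepl("^/product=", q))
          product <- gsub('"', "", sub("^/product=", "", q))
      }
      if (!is.na(locus_tag)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = locus_tag, replicon_id = replicon, rank = NA_integer_,
          start = min(nums), end = max(nums), strand = strand,
          product = product, stringsAsFactors = FALSE)
      }
    }
    i <- i + 1L
  }
  if (!length(out)) return(empty_gene_df())
  do.call(rbind, out)
}

parse_gene_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "replicon_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene TSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$product)) df$product <- NA_character_
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("gene TSV: start/end must be numeric", call. = FALSE)
  df$rank <- NA_integer_
  df[c("gene_id", "replicon_id", "rank", "start", "end", "strand", "product")]
}

#' Write a gene table to TSV
#'
#' Inverse of [read_gene_table()] with `format = "tsv"`: round-tripping is
#' content-identical up to column order.
#'
#' @param genes a `gene_table` data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  validate_gene_table(genes)
  utils::write.table(genes[c("gene_id", "replicon_id", "start", "end",
                             "strand", "product")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain-hit table
#'
#' Reads a dbCAN-style TSV with columns `gene_id`, `accession`, `tool`,
#' `evalue`. Tool names are normalised case-insensitively to
#' HMMER/DIAMOND/eCAMI/BLASTP and validated against the set allowed for the
#' source database (CAZy: HMMER/DIAMOND/eCAMI; Pfam/TIGRFAM: BLASTP/HMMER;
#' MEROPS/SulfAtlas: BLASTP).
#'
#' @param path path to the TSV.
#' @param source_db one of `"CAZy"`, `"Pfam"`, `"TIGRFAM"`, `"MEROPS"`,
#'   `"SulfAtlas"`.
#' @return a `domain_hits` data.frame with columns `gene_id`, `accession`,
#'   `tool`, `evalue`, `source_db`.
#' @export
read_hits <- function(path, source_db) {
  source_db <- match.arg(source_db, VALID_SOURCE_DBS)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "accession", "tool", "evalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hit TSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ev <- suppressWarnings(as.numeric(df$evalue))
  bad <- which(is.na(ev))
  if (length(bad))
    stop("non-numeric e-value at data row ", bad[1L], ": '",
         df$evalue[bad[1L]], "'", call. = FALSE)
  if (any(ev < 0)) stop("negative e-value", call. = FALSE)
  if (any(!nzchar(df$accession))) stop("empty accession", call. = FALSE)
  tool <- normalize_tool(df$tool)
  allowed <- TOOLS_BY_DB[[source_db]]
  bad <- which(!(tool %in% allowed))
  if (length(bad))
    stop("tool '", df$tool[bad[1L]], "' not allowed for source_db ", source_db,
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  hits <- data.frame(gene_id = df$gene_id, accession = df$accession,
                     tool = tool, evalue = ev, source_db = source_db,
                     stringsAsFactors = FALSE)
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

normalize_tool <- function(x) {
  canon <- setNames(VALID_TOOLS, toupper(VALID_TOOLS))
  out <- canon[toupper(x)]
  if (anyNA(out))
    stop("unknown tool name: ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  unname(out)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return an uppercased [Biostrings::DNAStringSet] named by replicon id
#'   (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @param rooted_binary if `TRUE` (default), require a strictly bifurcating
#'   rooted tree and fail with "non-binary" otherwise. Set to `FALSE` for
#'   unrooted gene trees destined for [root_search()].
#' @return an [ape::read.tree] `phylo` object.
#' @export
read_newick <- function(path, rooted_binary = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path, call. = FALSE)
  if (lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE))) !=
      lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE))))
    stop("unbalanced parentheses in ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("Newick parse failure in ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse failure in ", path, call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in ", path, call. = FALSE)
  if (rooted_binary && !(ape::is.rooted(tr) && ape::is.binary(tr)))
    stop("non-binary: tree in ", path,
         " must be strictly bifurcating and rooted", call. = FALSE)
  tr
}

#' Read a gene-tree-leaf to species map
#'
#' @param path TSV with columns `leaf`, `species`.
#' @return named character vector: `names()` are gene-tree leaves, values
#'   are species-tree leaves.
#' @export
read_leaf_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("leaf", "species") %in% names(df)))
    stop("leaf map TSV needs columns 'leaf' and 'species'", call. = FALSE)
  if (anyDuplicated(df$leaf)) stop("duplicate leaf in map", call. = FALSE)
  setNames(df$species, df$leaf)
}
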