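# Genome-level descriptive and comparative statistics: length, G+C, role
# densities per Mb, P/C ratio, fragment-based reciprocal best-hit ANI, and
# pairwise 16S identity. Rounding happens only at the reporting layer;
# internal values keep full precision.

as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
  stop("expected DNAStringSet / DNAString / character", call. = FALSE)
}

#' G+C content (percent)
#'
#' `100 * (G + C) / (A + C + G + T)`; IUPAC ambiguity codes are excluded
#' from numerator and denominator.
#'
#' @param seqs genome sequences (DNAStringSet, DNAString, or character).
#' @return percent, full precision (round to one decimal for reporting).
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seqs) {
  seqs <- as_dss(seqs)
  f <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  denom <- sum(f)
  if (denom == 0) stop("no unambiguous bases", call. = FALSE)
  100 * (f[["G"]] + f[["C"]]) / denom
}

#' Total genome length in bp
#'
#' Sum of replicon lengths, ambiguous bases included.
#'
#' @inheritParams gc_content
#' @export
genome_length <- function(seqs) {
  seqs <- as_dss(seqs)
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  sum(Biostrings::width(seqs))
}

#' Role densities and the P/C ratio
#'
#' Counts CAZymes (genes with a consensus family), peptidases, sulfatases,
#' SusC and SusD genes in a role table, and scales them per Mb. The P/C
#' ratio (peptidases / CAZymes) is `NA` when the genome has no CAZymes.
#'
#' @param roles a merged `gene_roles` table.
#' @param length_bp genome length in bp (> 0).
#' @return one-row data.frame with counts, per-Mb densities, `pc_ratio`,
#'   and per-class CAZyme assignment counts (`n_GH` ... `n_AA`).
#' @export
densities <- function(roles, length_bp) {
  stopifnot(length_bp > 0)
  mb <- length_bp / 1e6
  caz <- sum(nzchar(roles$cazyme_families))
  pep <- sum(roles$is_peptidase)
  sulf <- sum(roles$is_sulfatase)
  fams <- unlist(split_families(roles))
  cls <- c("GH", "GT", "PL", "CE", "CBM", "AA")
  class_counts <- vapply(cls, function(k)
    sum(sub("[0-9]+$", "", fams) == k), integer(1))
  out <- data.frame(
    length_bp = length_bp,
    cazyme_count = caz, peptidase_count = pep, sulfatase_count = sulf,
    susC_count = sum(roles$is_susC), susD_count = sum(roles$is_susD),
    cazyme_per_mb = caz / mb, peptidase_per_mb = pep / mb,
    sulfatase_per_mb = sulf / mb,
    pc_ratio = if (caz == 0) NA_real_ else pep / caz)
  for (k in cls) out[[paste0("n_", k)]] <- class_counts[[k]]
  out
}

#' Full per-genome statistics row
#'
#' @param genome_id genome label.
#' @param seqs genome sequences.
#' @param roles merged `gene_roles` table.
#' @export
genome_stats <- function(genome_id, seqs, roles) {
  len <- genome_length(seqs)
  cbind(data.frame(genome_id = genome_id, gc_percent = gc_content(seqs)),
        densities(roles, len))
}

#' ANI configuration
#'
#' Parameters of the fragment-based reciprocal best-hit ANI (OrthoANI-style
#' algorithm: both genomes are cut into consecutive non-overlapping
#' fragments, trailing remainders discarded; each fragment's best local
#' alignment against the other genome's fragment set is found in both
#' directions; ANI is the mean identity over reciprocal best-hit pairs).
#'
#' @param fragment_length fragment size in bp (default 1020).
#' @param reciprocal require reciprocal best hits (default TRUE; FALSE uses
#'   all best hits, mainly for diagnostics).
#' @param backend local-alignment backend behind the fragment-pair
#'   contract: `"blastn"` shells out to NCBI BLAST+ (what the published
#'   tool wraps; fast), `"biostrings"` uses in-process Smith-Waterman with
#'   exact k-mer seeding (no external binaries), `"auto"` (default) picks
#'   blastn when it is on the PATH.
#' @param kmer exact-seed length used to shortlist candidate fragment pairs
#'   before alignment (biostrings backend).
#' @param max_candidates alignments attempted per fragment (top candidates
#'   by shared-seed count; biostrings backend).
#' @param match,mismatch,gap_opening,gap_extension local-alignment scoring
#'   (biostrings backend).
#' @export
ani_config <- function(fragment_length = 1020L, reciprocal = TRUE,
                       backend = c("auto", "blastn", "biostrings"),
                       kmer = 13L, max_candidates = 8L,
                       match = 1, mismatch = -2,
                       gap_opening = 5, gap_extension = 2) {
  stopifnot(fragment_length > 0, kmer >= 8, max_candidates >= 1)
  backend <- match.arg(backend)
  if (backend == "auto")
    backend <- if (nzchar(Sys.which("blastn"))) "blastn" else "biostrings"
  structure(list(fragment_length = as.integer(fragment_length),
                 reciprocal = isTRUE(reciprocal), backend = backend,
                 kmer = as.integer(kmer),
                 max_candidates = as.integer(max_candidates),
                 match = match, mismatch = mismatch,
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "ani_config")
}

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Trailing remainders shorter than `fragment_length` are discarded, per
#' replicon.
#'
#' @inheritParams gc_content
#' @param fragment_length fragment size in bp.
#' @return DNAStringSet of fragments.
#' @export
fragment_genome <- function(seqs, fragment_length = 1020L) {
  seqs <- as_dss(seqs)
  frags <- lapply(seq_along(seqs), function(i) {
    w <- Biostrings::width(seqs)[i]
    n <- w %/% fragment_length
    if (n == 0L) return(Biostrings::DNAStringSet())
    starts <- (seq_len(n) - 1L) * fragment_length + 1L
    Biostrings::extractAt(seqs[[i]],
                          IRanges::IRanges(starts, width = fragment_length))
  })
  do.call(c, frags)
}

# k-mer shortlist: for each query fragment, candidate subject fragments with
# the number of distinct shared exact seeds. Subject k-mers are sampled
# every 2 positions, query k-mers every 4; the join is fully vectorised
# (integer codes + CSR expansion), so cost is linear in seed count.
kmer_candidates <- function(query, subject, k, max_candidates,
                            q_step = 4L, s_step = 2L) {
  subj_chr <- as.character(subject)
  qry_chr <- as.character(query)
  n_sub <- length(subj_chr); n_qry <- length(qry_chr)
  wid <- nchar(subj_chr[1L])
  s_starts <- seq(1L, wid - k + 1L, by = s_step)
  q_starts <- seq(1L, wid - k + 1L, by = q_step)
  s_km <- unlist(lapply(subj_chr, function(s)
    substring(s, s_starts, s_starts + k - 1L)), use.names = FALSE)
  s_frag <- rep(seq_len(n_sub), each = length(s_starts))
  q_km <- unlist(lapply(qry_chr, function(s)
    substring(s, q_starts, q_starts + k - 1L)), use.names = FALSE)
  q_frag <- rep(seq_len(n_qry), each = length(q_starts))
  u <- unique(s_km)
  sc <- match(s_km, u)
  qc <- match(q_km, u)
  # distinct (fragment, k-mer) pairs on both sides
  skey <- !duplicated((as.numeric(sc) - 1) * n_sub + s_frag)
  sc <- sc[skey]; s_frag <- s_frag[skey]
  ok <- !is.na(qc)
  qc <- qc[ok]; q_frag <- q_frag[ok]
  qkey <- !duplicated((as.numeric(qc) - 1) * n_qry + q_frag)
  qc <- qc[qkey]; q_frag <- q_frag[qkey]
  if (!length(qc)) return(vector("list", n_qry))
  # CSR over subject codes, then expand every query seed to its subject hits
  ord <- order(sc)
  sc_sorted <- sc[ord]; s_frag_sorted <- s_frag[ord]
  cnt <- tabulate(sc_sorted, nbins = length(u))
  starts <- c(0L, cumsum(cnt))[seq_along(cnt)] + 1L
  reps <- cnt[qc]
  pair_q <- rep(q_frag, reps)
  pair_s <- s_frag_sorted[sequence(reps, from = starts[qc])]
  key <- (pair_q - 1) * as.numeric(n_sub) + pair_s
  r <- rle(sort(key))
  kq <- as.integer((r$values - 1) %/% n_sub) + 1L
  ks <- as.integer((r$values - 1) %% n_sub) + 1L
  out <- vector("list", n_qry)
  for (grp in split(seq_along(kq), kq)) {
    i <- kq[grp[1L]]
    n_shared <- r$lengths[grp]
    ord2 <- order(-n_shared, ks[grp])
    idx <- ks[grp][ord2]; n_shared <- n_shared[ord2]
    # drop seed-poor candidates: spurious matches share a handful of seeds,
    # homologous fragments share many
    keep <- n_shared >= max(3, ceiling(0.25 * n_shared[1L]))
    out[[i]] <- utils::head(
      data.frame(idx = idx[keep], n_shared = n_shared[keep]), max_candidates)
  }
  out
}

# Local-alignment backend contract: given one query fragment and a set of
# subject fragments, return per-subject (score, identity). Implemented with
# Biostrings' C-level Smith-Waterman.
align_fragment <- function(query, subjects, config, submat) {
  aln <- Biostrings::pairwiseAlignment(
    subjects, query, type = "local", substitutionMatrix = submat,
    gapOpening = config$gap_opening, gapExtension = config$gap_extension)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1"))
}

# one direction of best-hit search: best subject fragment for every query
# fragment. Ties broken by identity, then lowest fragment index. Identical
# fragments short-circuit the aligner (maximal score, identity 100).
best_hits <- function(query, subject, config) {
  cands <- kmer_candidates(query, subject, config$kmer, config$max_candidates)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  qry_chr <- as.character(query); subj_chr <- as.character(subject)
  best_idx <- rep(NA_integer_, length(query))
  best_id <- numeric(length(query))
  for (i in seq_along(query)) {
    ci <- cands[[i]]
    if (is.null(ci) || !nrow(ci)) next
    exact <- ci$idx[subj_chr[ci$idx] == qry_chr[i]]
    if (length(exact)) {
      best_idx[i] <- min(exact); best_id[i] <- 100
      next
    }
    res <- align_fragment(query[[i]], subject[ci$idx], config, submat)
    ord <- order(-res$score, -res$identity, ci$idx)
    best_idx[i] <- ci$idx[ord[1L]]
    best_id[i] <- res$identity[ord[1L]]
  }
  list(idx = best_idx, identity = best_id)
}

#' OrthoANI-style average nucleotide identity
#'
#' See [ani_config()] for the algorithm. Symmetric by construction: the
#' value is the mean of the two directional identities over reciprocal
#' best-hit fragment pairs.
#'
#' @param genomeA,genomeB genome sequences.
#' @param config an [ani_config()].
#' @return ANI percent (full precision).
#' @export
orthoani <- function(genomeA, genomeB, config = ani_config()) {
  a <- as_dss(genomeA); b <- as_dss(genomeB)
  fl <- config$fragment_length
  if (genome_length(a) < 2L * fl || genome_length(b) < 2L * fl)
    stop("genomes must each be at least 2 x fragment_length", call. = FALSE)
  fa <- fragment_genome(a, fl); fb <- fragment_genome(b, fl)
  finder <- if (config$backend == "blastn") best_hits_blastn else best_hits
  ab <- finder(fa, fb, config)
  ba <- finder(fb, fa, config)
  if (config$reciprocal) {
    ia <- which(!is.na(ab$idx))
    recip <- ia[!is.na(ba$idx[ab$idx[ia]]) & ba$idx[ab$idx[ia]] == ia]
    if (!length(recip)) stop("genomes too divergent for ANI", call. = FALSE)
    mean(c(ab$identity[recip], ba$identity[ab$idx[recip]]))
  } else {
    ids <- c(ab$identity[!is.na(ab$idx)], ba$identity[!is.na(ba$idx)])
    if (!length(ids)) stop("genomes too divergent for ANI", call. = FALSE)
    mean(ids)
  }
}

# blastn backend for the fragment best-hit search: same contract as
# best_hits(). One blastn run per direction; best HSP per query by
# bitscore, ties by identity then lowest subject fragment index.
best_hits_blastn <- function(query, subject, config) {
  if (!nzchar(Sys.which("blastn")) || !nzchar(Sys.which("makeblastdb")))
    stop("blastn/makeblastdb not on PATH; use backend = 'biostrings'",
         call. = FALSE)
  td <- tempfile("ani_blast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  names(query) <- paste0("q", seq_along(query))
  names(subject) <- paste0("s", seq_along(subject))
  qf <- file.path(td, "query.fa"); sf <- file.path(td, "subject.fa")
  Biostrings::writeXStringSet(query, qf)
  Biostrings::writeXStringSet(subject, sf)
  out <- file.path(td, "hits.tsv")
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  st <- system2("blastn",
                c("-task", "blastn", "-query", qf, "-db", sf,
                  "-outfmt", shQuote("6 qseqid sseqid bitscore pident"),
                  "-max_target_seqs", "10", "-dust", "no",
                  "-num_threads", "1", "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed with status ", st, call. = FALSE)
  best_idx <- rep(NA_integer_, length(query))
  best_id <- numeric(length(query))
  if (file.size(out) > 0L) {
    tab <- utils::read.delim(out, header = FALSE,
                             col.names = c("q", "s", "bitscore", "pident"),
                             stringsAsFactors = FALSE)
    tab$qi <- as.integer(sub("^q", "", tab$q))
    tab$si <- as.integer(sub("^s", "", tab$s))
    tab <- tab[order(tab$qi, -tab$bitscore, -tab$pident, tab$si), ]
    tab <- tab[!duplicated(tab$qi), ]
    best_idx[tab$qi] <- tab$si
    best_id[tab$qi] <- tab$pident
  }
  list(idx = best_idx, identity = best_id)
}

#' Pairwise 16S rRNA identity
#'
#' Global alignment (Needleman-Wunsch); identity = matches / aligned
#' columns, where terminal overhangs (alignment ends where one sequence has
#' run out) are excluded and internal gap columns count in the denominator.
#'
#' @param seqA,seqB nucleotide sequences (character or DNAString).
#' @param match,mismatch,gap_opening,gap_extension scoring (defaults +1,
#'   -1, 2, 0.5; penalties positive).
#' @return identity percent (full precision).
#' @examples
#' pairwise_identity_16S("ACGT", "ACGA")  # 75
#' @export
pairwise_identity_16S <- function(seqA, seqB, match = 1, mismatch = -1,
                                  gap_opening = 2, gap_extension = 0.5) {
  a <- as_dss(seqA); b <- as_dss(seqB)
  if (length(a) != 1L || length(b) != 1L)
    stop("expected exactly one sequence per input", call. = FALSE)
  if (Biostrings::width(a) == 0L || Biostrings::width(b) == 0L)
    stop("empty sequence", call. = FALSE)
  if (min(Biostrings::width(a), Biostrings::width(b)) < 1000L)
    warning("sequence shorter than 1 kb; not a full-length 16S gene?",
            call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a[[1L]], b[[1L]], type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gap_a <- pa == "-"; gap_b <- pb == "-"
  # terminal overhang: maximal run of gap columns at either end
  non_gap <- which(!(gap_a | gap_b))
  lo <- non_gap[1L]; hi <- non_gap[length(non_gap)]
  cols <- lo:hi
  100 * sum(pa[cols] == pb[cols] & !gap_a[cols]) / length(cols)
}
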