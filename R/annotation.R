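# Consensus and marker rules turning raw domain hits into per-gene roles.
#
# A gene is a CAZyme of family F when at least `consensus_min_tools` of the
# dbCAN search tools (HMMER, DIAMOND, eCAMI) assign it an accession whose
# subfamily-stripped form is F ("GH16_3" votes for "GH16"). SusC/SusD are
# called from TIGRFAM/Pfam marker accessions, peptidases from MEROPS and
# sulfatases from SulfAtlas, all under a strict e < 1e-15 cutoff.

CAZY_FAMILY_RE <- "^(GH|GT|PL|CE|AA|CBM)[0-9]+$"

#' Marker/consensus configuration
#'
#' @param susC_accessions accessions whose presence marks a SusC-like
#'   TonB-dependent transporter. Default `TIGR04056`, `TIGR04057`.
#' @param susD_accessions accessions marking a SusD-like sugar-binding
#'   lipoprotein. Default `PF07980`, `PF12741`, `PF12771`.
#' @param evalue_cutoff strict upper bound on hit e-values for marker,
#'   peptidase and sulfatase calls (hits with `evalue >= cutoff` are
#'   ignored). Default `1e-15`.
#' @param consensus_min_tools number of distinct dbCAN tools that must agree
#'   on a (gene, family) assignment; default 2 of the 3.
#' @return a `marker_config` list.
#' @export
marker_config <- function(susC_accessions = c("TIGR04056", "TIGR04057"),
                          susD_accessions = c("PF07980", "PF12741", "PF12771"),
                          evalue_cutoff = 1e-15,
                          consensus_min_tools = 2L) {
  stopifnot(evalue_cutoff > 0, consensus_min_tools %in% 1:3,
            length(susC_accessions) >= 1, length(susD_accessions) >= 1)
  structure(list(susC_accessions = susC_accessions,
                 susD_accessions = susD_accessions,
                 evalue_cutoff = evalue_cutoff,
                 consensus_min_tools = as.integer(consensus_min_tools)),
            class = "marker_config")
}

#' Strip a CAZy subfamily suffix
#'
#' `"GH16_3"` becomes `"GH16"`; plain family names pass through.
#'
#' @param accession character vector of CAZy accessions.
#' @export
strip_subfamily <- function(accession) sub("_.*$", "", accession)

empty_roles <- function() {
  df <- data.frame(gene_id = character(), cazyme_families = character(),
                   is_susC = logical(), is_susD = logical(),
                   is_peptidase = logical(), is_sulfatase = logical(),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_roles", "data.frame")
  df
}

roles_row <- function(gene_id, families = "", susC = FALSE, susD = FALSE,
                      pep = FALSE, sulf = FALSE) {
  data.frame(gene_id = gene_id, cazyme_families = families,
             is_susC = susC, is_susD = susD, is_peptidase = pep,
             is_sulfatase = sulf, stringsAsFactors = FALSE)
}

finish_roles <- function(df) {
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_roles", "data.frame")
  df
}

#' Consensus CAZyme calls from multi-tool hits
#'
#' One vote per (gene, tool): the tool's best hit by e-value (ties broken
#' lexicographically by accession), subfamily-stripped. Families reaching
#' `consensus_min_tools` distinct tool votes are kept; genes reaching no
#' family threshold are not CAZymes. No e-value cutoff is applied here: the
#' upstream search tools apply their own significance filters.
#'
#' @param hits a `domain_hits` data.frame with `source_db == "CAZy"`.
#' @param config a [marker_config()].
#' @return a `gene_roles` fragment (CAZyme columns filled).
#' @export
consensus_cazymes <- function(hits, config = marker_config()) {
  stopifnot(inherits(config, "marker_config"))
  if (nrow(hits) == 0L) return(empty_roles())
  if (!all(hits$source_db == "CAZy"))
    stop("consensus_cazymes expects CAZy hits only", call. = FALSE)
  bad <- setdiff(unique(hits$tool), TOOLS_BY_DB$CAZy)
  if (length(bad))
    stop("unknown/invalid consensus tool: ", paste(bad, collapse = ", "),
         call. = FALSE)
  # best accession per (gene, tool): lowest e-value, then lexicographic
  h <- hits[order(hits$gene_id, hits$tool, hits$evalue, hits$accession), ]
  best <- h[!duplicated(h[c("gene_id", "tool")]), ]
  best$family <- strip_subfamily(best$accession)
  bad_fam <- !grepl(CAZY_FAMILY_RE, best$family)
  if (any(bad_fam)) {
    warning("ignoring non-CAZy accession(s): ",
            paste(unique(best$accession[bad_fam]), collapse = ", "),
            call. = FALSE)
    best <- best[!bad_fam, , drop = FALSE]
  }
  if (nrow(best) == 0L) return(empty_roles())
  votes <- unique(best[c("gene_id", "tool", "family")])
  tab <- stats::aggregate(tool ~ gene_id + family, data = votes,
                          FUN = function(x) length(unique(x)))
  tab <- tab[tab$tool >= config$consensus_min_tools, , drop = FALSE]
  if (nrow(tab) == 0L) return(empty_roles())
  fams <- vapply(split(tab$family, tab$gene_id),
                 function(f) paste(sort(unique(f)), collapse = ","),
                 character(1))
  finish_roles(roles_row(names(fams), families = unname(fams)))
}

#' SusC/SusD marker calls
#'
#' A gene is SusC when it carries at least one hit on a `susC_accessions`
#' model with `evalue < evalue_cutoff`; SusD analogously. A gene hit by both
#' marker sets is called SusC only (the TonB-dependent receptor models are
#' the more specific evidence) with a warning.
#'
#' @param hits `domain_hits` from Pfam and/or TIGRFAM searches.
#' @param config a [marker_config()].
#' @return a `gene_roles` fragment (`is_susC`/`is_susD` filled).
#' @export
call_susCD <- function(hits, config = marker_config()) {
  stopifnot(inherits(config, "marker_config"))
  if (nrow(hits) == 0L) return(empty_roles())
  ok <- hits$evalue < config$evalue_cutoff
  susC <- unique(hits$gene_id[ok & hits$accession %in% config$susC_accessions])
  susD <- unique(hits$gene_id[ok & hits$accession %in% config$susD_accessions])
  both <- intersect(susC, susD)
  if (length(both)) {
    warning("gene(s) with both SusC and SusD markers called SusC: ",
            paste(both, collapse = ", "), call. = FALSE)
    susD <- setdiff(susD, both)
  }
  genes <- sort(unique(c(susC, susD)))
  if (!length(genes)) return(empty_roles())
  finish_roles(roles_row(genes, susC = genes %in% susC, susD = genes %in% susD))
}

#' Peptidase/sulfatase calls from BLASTP hits
#'
#' A gene is flagged iff its best e-value against the respective database is
#' strictly below `evalue_cutoff` (MEROPS for peptidases, SulfAtlas for
#' sulfatases).
#'
#' @param hits `domain_hits` with `source_db` MEROPS and/or SulfAtlas.
#' @param config a [marker_config()].
#' @return a `gene_roles` fragment.
#' @export
call_peptidases_sulfatases <- function(hits, config = marker_config()) {
  stopifnot(inherits(config, "marker_config"))
  if (nrow(hits) == 0L) return(empty_roles())
  ok <- hits$evalue < config$evalue_cutoff
  pep <- unique(hits$gene_id[ok & hits$source_db == "MEROPS"])
  sulf <- unique(hits$gene_id[ok & hits$source_db == "SulfAtlas"])
  genes <- sort(unique(c(pep, sulf)))
  if (!length(genes)) return(empty_roles())
  finish_roles(roles_row(genes, pep = genes %in% pep, sulf = genes %in% sulf))
}

#' Merge role fragments into one role table
#'
#' Takes the union of roles per gene across fragments. CAZyme family sets
#' are unioned; boolean roles are OR-ed. If the merge would leave a gene
#' flagged both SusC and SusD, SusC wins and a warning is raised.
#'
#' @param ... `gene_roles` fragments from the same genome.
#' @return a merged `gene_roles` data.frame ordered by `gene_id`.
#' @export
merge_roles <- function(...) {
  frags <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(frags)) return(empty_roles())
  all <- do.call(rbind, lapply(frags, as.data.frame))
  merged <- lapply(split(all, all$gene_id), function(g) {
    fams <- unique(unlist(strsplit(g$cazyme_families[nzchar(g$cazyme_families)], ",")))
    roles_row(g$gene_id[1L],
              families = paste(sort(fams), collapse = ","),
              susC = any(g$is_susC), susD = any(g$is_susD),
              pep = any(g$is_peptidase), sulf = any(g$is_sulfatase))
  })
  out <- do.call(rbind, merged)
  both <- out$is_susC & out$is_susD
  if (any(both)) {
    warning("gene(s) with both SusC and SusD roles resolved to SusC: ",
            paste(out$gene_id[both], collapse = ", "), call. = FALSE)
    out$is_susD[both] <- FALSE
  }
  finish_roles(out)
}

#' Write / read a role table TSV
#'
#' @param roles a `gene_roles` data.frame.
#' @param path TSV path.
#' @export
write_roles <- function(roles, path) {
  utils::write.table(as.data.frame(roles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roles
#' @export
read_roles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         cazyme_families = "character"))
  df$cazyme_families[is.na(df$cazyme_families)] <- ""
  finish_roles(df)
}

# family strings helper: list of character vectors per row
split_families <- function(roles) {
  out <- strsplit(roles$cazyme_families, ",", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}
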