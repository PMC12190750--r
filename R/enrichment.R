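# Hypergeometric gene-set enrichment of genes carrying differentially
# modified sites, against the universe of genes with tested sites.

#' Hit genes and universe for enrichment testing
#'
#' Maps site references (transcripts) to genes and returns, per modification
#' code, the set of genes carrying at least one differentially modified site
#' and the universe of genes carrying at least one tested site. References
#' absent from the gene map are excluded and reported.
#'
#' @param dms A `dms_table` (see [call_dms()]).
#' @param gene_map Data frame with columns `transcript_id` and `gene_id`
#'   (see [read_gene_map()]).
#' @return Named list (per mod code) of lists with `hits`, `universe` and
#'   `unmapped` (character vectors of gene / reference ids).
#' @export
genes_with_dms <- function(dms, gene_map) {
  if (is.null(gene_map) || nrow(gene_map) == 0L) stop("gene map is empty")
  gene <- gene_map$gene_id[match(dms$reference, gene_map$transcript_id)]
  unmapped <- unique(dms$reference[is.na(gene)])
  if (length(unmapped)) {
    message(length(unmapped), " reference(s) missing from the gene map were excluded")
  }
  out <- list()
  for (mc in unique(dms$mod_code)) {
    i <- dms$mod_code == mc & !is.na(gene)
    out[[mc]] <- list(
      hits = unique(gene[i & dms$is_dms]),
      universe = unique(gene[i]),
      unmapped = unmapped
    )
  }
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `n_overlap` gene-set members among the
#' hit genes when drawing `n_hits` genes without replacement from a universe
#' of `n_universe` genes containing `n_set_in_universe` set members:
#' `P(X >= n_overlap)`, the standard over-representation ("success") tail.
#'
#' @param n_overlap Hits that are set members.
#' @param n_hits Number of hit genes drawn.
#' @param n_set_in_universe Set members in the universe.
#' @param n_universe Universe size.
#' @return Upper-tail P-value.
#' @export
hypergeom_test <- function(n_overlap, n_hits, n_set_in_universe, n_universe) {
  stopifnot(n_universe >= 0, n_hits >= 0, n_set_in_universe >= 0, n_overlap >= 0)
  if (n_hits > n_universe || n_set_in_universe > n_universe)
    stop("margins exceed the universe size")
  if (n_overlap > min(n_hits, n_set_in_universe))
    stop("overlap exceeds a margin")
  stats::phyper(n_overlap - 1, n_set_in_universe,
                n_universe - n_set_in_universe, n_hits, lower.tail = FALSE)
}

#' Gene-set enrichment of differentially modified genes
#'
#' Runs the hypergeometric test for every (modification code, gene set) pair
#' and adjusts all tests jointly by Benjamini-Hochberg.
#'
#' @param dms A `dms_table`.
#' @param gene_map Transcript-to-gene map (see [read_gene_map()]).
#' @param gene_sets Named list of character vectors of gene ids (see
#'   [read_gene_sets()]).
#' @return Data frame with one row per (mod code, set): universe and margin
#'   sizes, overlap, `p` and BH `q`.
#' @export
enrich_gene_sets <- function(dms, gene_map, gene_sets) {
  stopifnot(length(gene_sets) >= 1L)
  hits <- genes_with_dms(dms, gene_map)
  rows <- list()
  for (mc in names(hits)) {
    uni <- hits[[mc]]$universe
    hh <- hits[[mc]]$hits
    for (sn in names(gene_sets)) {
      set_in_uni <- intersect(gene_sets[[sn]], uni)
      overlap <- intersect(hh, set_in_uni)
      rows[[length(rows) + 1L]] <- data.frame(
        mod_code = mc, set_name = sn,
        n_universe = length(uni), n_set_in_universe = length(set_in_uni),
        n_hits = length(hh), n_overlap = length(overlap),
        p = hypergeom_test(length(overlap), length(hh),
                           length(set_in_uni), length(uni)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
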