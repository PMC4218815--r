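#' Hypergeometric over-representation of a gene list
#'
#' Upper-tail hypergeometric test `P(X >= k)` per term, with universe size
#' `N`, term size `K` (after restriction to the universe), list size `n`
#' and overlap `k`. Terms with `k = 0` are omitted from the result (their
#' p is 1 by construction). Terms empty after restriction to the universe
#' are dropped.
#'
#' @param gene_list Character vector of genes (e.g. up- or down-regulated
#'   consensus genes); must be a subset of the universe.
#' @param collection A list with `sets` (named list term -> member genes)
#'   and `universe` (character vector), e.g. from [build_gene_sets()] or
#'   assembled from [fgsea::gmtPathways()] output.
#' @param direction Label attached to the records (`"up"`, `"down"`, ...).
#' @return A data.frame of class `enrichment_records`: `term_id`,
#'   `direction`, `k`, `n`, `K`, `N`, `p`, `q` (BH across tested terms),
#'   `overlap_genes` (comma-joined).
#' @examples
#' coll <- list(sets = list(t1 = c("g1", "g2", "g3")), universe = paste0("g", 1:10))
#' enrich(c("g1", "g2"), coll, "up")
#' @export
enrich <- function(gene_list, collection, direction = "up") {
  universe <- unique(collection$universe)
  missing <- setdiff(gene_list, universe)
  if (length(missing))
    stop("genes absent from the universe: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  gene_list <- unique(gene_list)
  n <- length(gene_list)
  N <- length(universe)
  sets <- lapply(collection$sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  rec <- lapply(names(sets), function(tid) {
    members <- sets[[tid]]
    ov <- intersect(gene_list, members)
    k <- length(ov)
    if (k == 0) return(NULL)
    K <- length(members)
    data.frame(term_id = tid, direction = direction, k = k, n = n, K = K,
               N = N, p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  if (is.null(out))
    out <- data.frame(term_id = character(0), direction = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_records", "data.frame"))
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)` -- the containment-style sharing
#' measure used to link enriched terms into clusters. A Jaccard variant
#' (`|A intersect B| / |A union B|`) is available via `method`.
#'
#' @param term_a,term_b Non-empty character vectors of member genes.
#' @param method `"min"` (overlap coefficient, default) or `"jaccard"`.
#' @return A proportion in `[0, 1]`.
#' @export
overlap_coefficient <- function(term_a, term_b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  a <- unique(term_a); b <- unique(term_b)
  if (!length(a) || !length(b)) stop("overlap coefficient of an empty set")
  i <- length(intersect(a, b))
  if (method == "min") i / min(length(a), length(b))
  else i / length(union(a, b))
}

#' Cluster significant terms by membership overlap and filter the report
#'
#' Restricts enrichment records to `p <= p_max`, links two terms when
#' their membership overlap is at least `theta`, reports only terms with
#' at least one such partner (the "at least 30% overlap with at least one
#' other category" rule), and returns connected components of the overlap
#' graph as term clusters. Singleton terms (no partner) are kept in a side
#' table but excluded from the report.
#'
#' @param records [enrich()] output (up and down records may be
#'   concatenated with `rbind` first; terms are compared within the table).
#' @param collection The gene-set collection the records were computed
#'   against (memberships define the overlaps).
#' @param theta Overlap threshold (default 0.30).
#' @param p_max Significance cutoff on the raw hypergeometric p
#'   (default 0.05; the quoted rule uses raw p, q is reported alongside).
#' @param method Overlap denominator, see [overlap_coefficient()].
#' @return A list of class `term_clusters`: `report` (records with
#'   `cluster_id`), `singletons`, `clusters` (list of term-id vectors),
#'   `overlap` (pairwise matrix on the significant terms), `theta`, `p_max`.
#' @export
cluster_and_filter <- function(records, collection, theta = 0.30,
                               p_max = 0.05, method = c("min", "jaccard")) {
  method <- match.arg(method)
  sig <- records[records$p <= p_max, , drop = FALSE]
  # direction-specific records of the same term count once in the graph
  terms <- unique(sig$term_id)
  nt <- length(terms)
  ov <- matrix(0, nt, nt, dimnames = list(terms, terms))
  universe <- unique(collection$universe)
  memb <- lapply(collection$sets[terms], function(s) intersect(unique(s), universe))
  if (nt > 1) {
    for (i in seq_len(nt - 1)) {
      for (j in seq.int(i + 1, nt)) {
        ov[i, j] <- ov[j, i] <-
          overlap_coefficient(memb[[i]], memb[[j]], method = method)
      }
    }
  }
  diag(ov) <- 1
  adj <- ov >= theta
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  degree <- igraph::degree(g)
  connected <- names(degree)[degree >= 1]
  cluster_of <- setNames(comp$membership, terms)

  report <- sig[sig$term_id %in% connected, , drop = FALSE]
  report$cluster_id <- unname(cluster_of[report$term_id])
  singletons <- sig[!(sig$term_id %in% connected), , drop = FALSE]
  clusters <- split(terms, cluster_of)
  clusters <- clusters[vapply(clusters, length, 1L) >= 2]
  structure(list(report = report, singletons = singletons,
                 clusters = unname(clusters), overlap = ov,
                 theta = theta, p_max = p_max),
            class = "term_clusters")
}
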