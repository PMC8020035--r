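# Pathway analysis: hypergeometric over-representation and topology
# impact via relative betweenness centrality over a bundled pathway
# graph library (a static JSON fixture; no live database access).

#' Load a pathway graph library
#'
#' The library is a JSON file with a `background` compound universe and
#' a list of pathways, each with `id`, `name`, `nodes` (compound IDs),
#' and undirected `edges` (pairs of node IDs). The bundled fixture
#' ships about a dozen small toy pathway graphs.
#'
#' @param path JSON file; default is the bundled fixture.
#' @return List of class `pathway_library`: `background`, `pathways`
#'   (each a `pathway_graph` list).
#' @export
load_pathway_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathway_library.json",
                        package = "urometab", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  background <- unlist(raw$background)
  pathways <- lapply(raw$pathways, function(p) {
    nodes <- unlist(p$nodes)
    edges <- if (length(p$edges)) {
      do.call(rbind, lapply(p$edges, function(e) unlist(e)))
    } else matrix(character(), 0L, 2L)
    if (nrow(edges) && !all(edges %in% nodes)) {
      stop("pathway ", p$id, " has edges referencing unknown nodes")
    }
    if (!all(nodes %in% background)) {
      stop("pathway ", p$id, " has nodes outside the background universe")
    }
    structure(list(id = p$id, name = p$name, nodes = nodes,
                   edges = edges),
              class = "pathway_graph")
  })
  structure(list(background = background, pathways = pathways),
            class = "pathway_library")
}

#' Hypergeometric over-representation p-value
#'
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least `k` pathway members when `n` significant compounds
#' are drawn from a background of `N` compounds of which `K` belong to
#' the pathway. The upper tail is summed exactly.
#'
#' @param k hits in the pathway.
#' @param K pathway size (members in the background).
#' @param n total significant compounds (draws).
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hypergeometric_ora(5, 5, 5, 20) # 1 / choose(20, 5)
hypergeometric_ora <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1) stop("counts must be non-negative")
  if (k > min(K, n) || K > N || n > N) {
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

#' Pathway topology impact from relative betweenness centrality
#'
#' impact = sum of betweenness centralities of the matched nodes divided
#' by the sum over all pathway nodes. Pathways whose betweenness is zero
#' everywhere (e.g. complete graphs or isolated nodes) fall back to
#' degree centrality; if that is also all-zero (edgeless pathway) the
#' impact is the matched fraction of nodes.
#'
#' @param pathway a `pathway_graph`.
#' @param matched compound IDs, must all be pathway nodes.
#' @return Impact in \[0, 1\].
#' @export
relative_betweenness_impact <- function(pathway, matched) {
  stopifnot(inherits(pathway, "pathway_graph"))
  absent <- setdiff(matched, pathway$nodes)
  if (length(absent)) {
    stop("matched compounds absent from the pathway: ",
         paste(absent, collapse = ", "))
  }
  if (!length(matched)) return(0)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = pathway$nodes, stringsAsFactors = FALSE))
  cent <- igraph::betweenness(g, directed = FALSE)
  if (all(cent == 0)) cent <- igraph::degree(g)
  total <- sum(cent)
  if (total == 0) return(length(matched) / length(pathway$nodes))
  sum(cent[matched]) / total
}

#' Pathway over-representation and topology screen
#'
#' Runs the hypergeometric test and the relative-betweenness impact for
#' every pathway against the significant-compound list. Compounds absent
#' from the background universe are dropped with a warning (identifier-
#' mapping misses). No multiple-testing correction is applied by default,
#' matching raw per-pathway reporting; `holm = TRUE` adds Holm-adjusted
#' p-values.
#'
#' @param significant_compounds compound IDs found significantly altered.
#' @param library a `pathway_library`.
#' @param alpha significance level recorded on the results.
#' @param holm add a Holm-adjusted p-value column.
#' @return Data frame of class `pathway_screen`: pathway id, name, hits,
#'   size, background size, `p`, `impact`, matched compound IDs
#'   (comma-separated), sorted by p (ties by impact descending).
#' @export
pathway_screen <- function(significant_compounds,
                           library = load_pathway_library(),
                           alpha = 0.05, holm = FALSE) {
  stopifnot(inherits(library, "pathway_library"))
  bg <- library$background
  if (!length(bg)) stop("background universe is empty")
  sig <- unique(significant_compounds)
  unknown <- setdiff(sig, bg)
  if (length(unknown)) {
    warning("dropping compounds absent from the background: ",
            paste(unknown, collapse = ", "))
    sig <- intersect(sig, bg)
  }
  n <- length(sig)
  rows <- lapply(library$pathways, function(pw) {
    members <- intersect(pw$nodes, bg)
    matched <- intersect(sig, members)
    p <- hypergeometric_ora(length(matched), length(members), n,
                            length(bg))
    impact <- relative_betweenness_impact(pw, matched)
    data.frame(id = pw$id, name = pw$name, hits = length(matched),
               size = length(members), background = length(bg),
               p = p, impact = impact,
               matched = paste(matched, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, "holm")
  out <- out[order(out$p, -out$impact, out$id), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("pathway_screen", "data.frame")
  out
}
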