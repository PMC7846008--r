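# Cluster-level region algebra: unions, IDR/DtO split, NDI, interface
# hierarchy, connected spatial regions, DtO-in-interface frequencies.

.union_sets <- function(sets) {
  v <- unlist(sets, use.names = FALSE)
  if (is.null(v)) integer(0) else sort(unique(v))
}

#' Cluster-wide region unions and the IDR/DtO split
#'
#' UIR, UMR and USDR(theta) are at-least-once unions of the mapped member
#' interface, missing and soft sets. A position is IDR when it is missing in
#' every member whose alignment covers it; DtO is the remainder of the UMR
#' (missing somewhere, structured elsewhere).
#'
#' @param cluster a `Cluster`.
#' @return list with `UIR`, `UMR`, `USDR` (named list per threshold), `IDR`,
#'   `DtO`, all integer position sets on the reference sequence, plus
#'   `L_ref`.
#' @export
region_unions <- function(cluster) {
  L <- nchar(cluster$reference_sequence)
  mem <- cluster$members
  UIR <- .union_sets(lapply(mem, `[[`, "interface"))
  UMR <- .union_sets(lapply(mem, `[[`, "missing"))
  thetas <- names(mem[[1]]$soft)
  USDR <- lapply(thetas, function(th)
    .union_sets(lapply(mem, function(m) m$soft[[th]])))
  names(USDR) <- thetas

  cov_count <- integer(L)
  miss_count <- integer(L)
  for (m in mem) {
    cov_count[m$covered] <- cov_count[m$covered] + 1L
    miss_count[m$missing] <- miss_count[m$missing] + 1L
  }
  IDR <- UMR[miss_count[UMR] == cov_count[UMR]]
  DtO <- setdiff(UMR, IDR)
  list(UIR = UIR, UMR = UMR, USDR = USDR, IDR = IDR, DtO = DtO, L_ref = L)
}

#' Number of distinct interfaces of a cluster
#'
#' Two member interfaces are the same when their symmetric difference is at
#' most `diff_frac` of the reference length. A minimal representative group
#' is extracted greedily: nonempty mapped member interfaces are visited in
#' order of decreasing size (ties by member label) and one joins the
#' distinct set iff it differs from every interface already selected by more
#' than `diff_frac * L_ref` positions.
#'
#' @param cluster a `Cluster`.
#' @param diff_frac dissimilarity threshold as a fraction of the reference
#'   length (default 0.05; a 0.01 variant is supported).
#' @return list with integer `ndi` and `interfaces`, a named list of the
#'   selected position sets (names are member labels). `ndi` is 0 when no
#'   member is bound.
#' @export
count_ndi <- function(cluster, diff_frac = 0.05) {
  L <- nchar(cluster$reference_sequence)
  irs <- lapply(cluster$members, `[[`, "interface")
  labs <- vapply(cluster$members, `[[`, character(1), "label")
  nonempty <- lengths(irs) > 0L
  irs <- irs[nonempty]
  labs <- labs[nonempty]
  if (!length(irs)) return(list(ndi = 0L, interfaces = list()))
  ord <- order(-lengths(irs), labs)
  irs <- irs[ord]
  labs <- labs[ord]
  tol <- diff_frac * L
  selected <- list()
  for (k in seq_along(irs)) {
    distinct <- all(vapply(selected, function(s)
      length(union(s, irs[[k]])) - length(intersect(s, irs[[k]])) > tol,
      logical(1)))
    if (distinct) selected[[labs[k]]] <- irs[[k]]
  }
  list(ndi = length(selected), interfaces = selected)
}

#' Containment hierarchy of distinct interfaces
#'
#' Builds a directed acyclic graph over the distinct interfaces: an edge
#' A -> B is drawn when B contains A up to tolerance (`|A \ B| <= tol`) and
#' adds material (`|B \ A| >= tol`), with `tol = tol_frac * L_ref`; the
#' transitive reduction is then applied. Since every edge strictly increases
#' the set size, the graph is acyclic by construction (a defensive check
#' breaks any residual cycle by keeping the smaller-to-larger edge).
#'
#' @param distinct_interfaces named list of position sets (e.g. from
#'   [count_ndi()]).
#' @param L_ref reference sequence length.
#' @param tol_frac containment tolerance as a fraction of `L_ref`
#'   (default 0.05).
#' @return an `igraph` directed graph with one vertex per interface.
#' @export
interface_hierarchy <- function(distinct_interfaces, L_ref, tol_frac = 0.05) {
  n <- length(distinct_interfaces)
  labs <- names(distinct_interfaces)
  if (is.null(labs)) labs <- paste0("I", seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  if (n < 2L) return(g)
  tol <- tol_frac * L_ref
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      A <- distinct_interfaces[[i]]
      B <- distinct_interfaces[[j]]
      if (length(setdiff(A, B)) <= tol && length(setdiff(B, A)) >= tol)
        edges <- c(edges, i, j)
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  if (!igraph::is_dag(g)) {
    # near-equal sets could in principle produce a cycle; keep only edges
    # from the strictly smaller to the larger set
    el <- igraph::as_edgelist(g, names = FALSE)
    bad <- lengths(distinct_interfaces)[el[, 1]] >=
      lengths(distinct_interfaces)[el[, 2]]
    if (any(bad)) {
      message("interface_hierarchy: breaking cycle(s) among near-equal sets")
      g <- igraph::delete_edges(g, which(bad))
    }
  }
  .transitive_reduction(g)
}

.transitive_reduction <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  drop <- integer(0)
  for (e in seq_len(nrow(el))) {
    g2 <- igraph::delete_edges(g, e)
    d <- igraph::distances(g2, v = el[e, 1], to = el[e, 2], mode = "out")
    if (is.finite(d[1, 1])) drop <- c(drop, e)
  }
  if (length(drop)) g <- igraph::delete_edges(g, drop)
  g
}

#' Number of structurally connected regions of a position set
#'
#' Single-linkage grouping of the given reference positions on the
#' representative structure: two positions belong to the same region when
#' their Calpha atoms are within `cutoff` of each other, applied
#' recursively. Positions without coordinates (e.g. missing in the
#' representative) are skipped.
#'
#' @param positions integer positions on the reference sequence.
#' @param reference_structure `ChainStructure` of the representative.
#' @param cutoff linkage distance in Angstrom (default 6.0).
#' @return integer number of connected regions.
#' @export
connected_regions <- function(positions, reference_structure, cutoff = 6.0) {
  if (!length(positions)) return(0L)
  r <- reference_structure$residues
  pos <- positions[positions <= nrow(r)]
  pos <- pos[!is.na(r$x[pos])]
  if (!length(pos)) return(0L)
  xyz <- cbind(r$x[pos], r$y[pos], r$z[pos])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff + 1e-9
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' How often DtO residues sit in an interface when structured
#'
#' For each DtO position, the fraction of member structures in which the
#' position is modelled (not missing) and flagged as interface, over the
#' members in which it is modelled. Also reports the fraction of DtO
#' positions that are interface in more than half of their structured
#' occurrences.
#'
#' @param cluster a `Cluster`.
#' @param dto optional precomputed DtO set (from [region_unions()]).
#' @return list with `freq` (named numeric vector per DtO position),
#'   `median` and `frac_majority` (share of DtO positions with
#'   frequency > 1/2).
#' @export
dto_interface_frequencies <- function(cluster, dto = NULL) {
  if (is.null(dto)) dto <- region_unions(cluster)$DtO
  if (!length(dto))
    return(list(freq = numeric(0), median = NA_real_,
                frac_majority = NA_real_))
  structured <- integer(length(dto))
  in_ir <- integer(length(dto))
  for (m in cluster$members) {
    s <- dto %in% m$covered & !(dto %in% m$missing)
    structured <- structured + s
    in_ir <- in_ir + (s & dto %in% m$interface)
  }
  freq <- ifelse(structured > 0L, in_ir / structured, NA_real_)
  names(freq) <- as.character(dto)
  ok <- !is.na(freq)
  list(
    freq = freq,
    median = if (any(ok)) median(freq[ok]) else NA_real_,
    frac_majority = if (any(ok)) mean(freq[ok] > 0.5) else NA_real_
  )
}

#' Union of soft disorder over unbound members only
#'
#' @param cluster a `Cluster`.
#' @param theta threshold (must be one of the annotated thresholds).
#' @return list with `present` (any unbound member?) and `positions`.
#' @export
unbound_usdr <- function(cluster, theta = 1) {
  th <- as.character(theta)
  unb <- Filter(function(m) !m$bound, cluster$members)
  if (!length(unb)) return(list(present = FALSE, positions = integer(0)))
  list(present = TRUE,
       positions = .union_sets(lapply(unb, function(m) m$soft[[th]])))
}

#' Full cluster summary
#'
#' Region unions, relative sizes, NDI and distinct interfaces, the interface
#' hierarchy, connected-region counts for UIR and USDR, unbound-only USDR
#' and DtO interface frequencies.
#'
#' @param cluster a `Cluster`.
#' @param diff_frac NDI dissimilarity threshold (default 0.05).
#' @param region_cutoff Calpha linkage cutoff for connected regions
#'   (default 6.0).
#' @param theta_primary threshold used for the USDR-based quantities
#'   (default 1).
#' @return object of class `ClusterSummary`.
#' @export
summarize_cluster <- function(cluster, diff_frac = 0.05, region_cutoff = 6.0,
                              theta_primary = 1) {
  un <- region_unions(cluster)
  nd <- count_ndi(cluster, diff_frac = diff_frac)
  hier <- interface_hierarchy(nd$interfaces, un$L_ref, tol_frac = diff_frac)
  th <- as.character(theta_primary)
  usdr1 <- un$USDR[[th]]
  if (is.null(usdr1)) stop("theta_primary not among annotated thresholds")
  nr_uir <- nr_usdr <- NA_integer_
  if (!is.null(cluster$reference_structure)) {
    nr_uir <- connected_regions(un$UIR, cluster$reference_structure,
                                cutoff = region_cutoff)
    nr_usdr <- connected_regions(usdr1, cluster$reference_structure,
                                 cutoff = region_cutoff)
  }
  structure(
    list(
      cluster_id = cluster$cluster_id,
      L_ref = un$L_ref,
      n_structures = cluster$n_structures,
      n_unbound = cluster$n_unbound,
      UIR = un$UIR, UMR = un$UMR, USDR = un$USDR,
      IDR = un$IDR, DtO = un$DtO,
      r_I = length(un$UIR) / un$L_ref,
      r_D = length(usdr1) / un$L_ref,
      NDI = nd$ndi,
      distinct_interfaces = nd$interfaces,
      hierarchy = hier,
      n_regions_UIR = nr_uir,
      n_regions_USDR = nr_usdr,
      unbound_USDR = unbound_usdr(cluster, theta_primary),
      dto_freq = dto_interface_frequencies(cluster, un$DtO),
      theta_primary = theta_primary
    ),
    class = "ClusterSummary"
  )
}

#' @export
print.ClusterSummary <- function(x, ...) {
  cat(sprintf(
    "<ClusterSummary %s: L=%d, NDI=%d, r_I=%.3f, r_D=%.3f, |DtO|=%d, |IDR|=%d>\n",
    x$cluster_id, x$L_ref, x$NDI, x$r_I, x$r_D,
    length(x$DtO), length(x$IDR)))
  invisible(x)
}

#' Write a cluster summary as JSON, TSV and DOT
#'
#' The TSV holds one row per reference position with the region flags; the
#' hierarchy is exported in GraphViz DOT format.
#'
#' @param summary a `ClusterSummary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, summary$cluster_id)
  obj <- summary
  obj$hierarchy <- igraph::as_edgelist(summary$hierarchy)
  obj$unbound_USDR <- summary$unbound_USDR$positions
  obj$dto_freq <- unname(summary$dto_freq$freq)
  class(obj) <- NULL
  jsonlite::write_json(obj, paste0(base, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  L <- summary$L_ref
  df <- data.frame(position = seq_len(L))
  df$UIR <- as.integer(seq_len(L) %in% summary$UIR)
  df$UMR <- as.integer(seq_len(L) %in% summary$UMR)
  for (th in names(summary$USDR))
    df[[paste0("USDR_", th)]] <- as.integer(seq_len(L) %in% summary$USDR[[th]])
  df$IDR <- as.integer(seq_len(L) %in% summary$IDR)
  df$DtO <- as.integer(seq_len(L) %in% summary$DtO)
  write.table(df, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(summary$hierarchy, paste0(base, ".dot"), format = "dot")
  invisible(paste0(base, c(".json", ".tsv", ".dot")))
}
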