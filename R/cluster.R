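# Near-identical-chain clustering and annotation mapping onto the
# cluster representative.

.quality_order <- function(annotations) {
  res <- vapply(annotations, function(a)
    ifelse(is.na(a$resolution), Inf, a$resolution), numeric(1))
  rv <- vapply(annotations, function(a)
    ifelse(is.na(a$r_value), Inf, a$r_value), numeric(1))
  lab <- vapply(annotations, function(a) a$label, character(1))
  order(res, rv, lab)
}

#' Greedy clustering of near-identical chains
#'
#' Chains are sorted by structure quality (resolution ascending, then
#' R-value ascending, then label) and greedily assigned: each chain joins
#' the first existing cluster whose seed chain satisfies both the identity
#' and the length-ratio threshold, otherwise it founds a new cluster. The
#' result is a deterministic partition.
#'
#' @param annotations list of `ChainAnnotation` (each carries its sequence
#'   and structure-quality metadata).
#' @param id_min minimum sequence identity (default 0.90).
#' @param len_ratio_min minimum length ratio (default 0.90).
#' @return list of clusters, each a list of `ChainAnnotation`; within each
#'   cluster the seed (best-quality) chain comes first.
#' @export
build_clusters <- function(annotations, id_min = 0.90, len_ratio_min = 0.90) {
  stopifnot(length(annotations) >= 1L)
  ord <- .quality_order(annotations)
  seeds <- list()
  members <- list()
  for (k in ord) {
    a <- annotations[[k]]
    placed <- FALSE
    for (ci in seq_along(seeds)) {
      pid <- pairwise_identity(a$sequence, seeds[[ci]]$sequence)
      if (pid["identity"] >= id_min && pid["length_ratio"] >= len_ratio_min) {
        members[[ci]] <- c(members[[ci]], list(a))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds[[length(seeds) + 1L]] <- a
      members[[length(members) + 1L]] <- list(a)
    }
  }
  members
}

#' Select the representative member of a cluster
#'
#' In `"best"` mode the member with the numerically smallest resolution wins
#' (missing resolutions sort last), ties broken by smallest R-value, then by
#' label; `"random"` mode draws uniformly with the given seed.
#'
#' @param members list of `ChainAnnotation`.
#' @param mode `"best"` or `"random"`.
#' @param seed integer seed, required for `"random"`.
#' @return index of the representative within `members`.
#' @export
select_representative <- function(members, mode = c("best", "random"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(members) >= 1L)
  if (mode == "best") return(.quality_order(members)[1L])
  stopifnot(!is.null(seed))
  withr::with_seed(seed, sample.int(length(members), 1L))
}

#' Map a member annotation onto the reference sequence
#'
#' Aligns the member sequence globally against the reference (match = 1,
#' mismatch = 0, gap = 0; deterministic traceback) and transfers every
#' flagged position to its aligned reference position; positions aligned to
#' gaps are dropped.
#'
#' @param ann a `ChainAnnotation`.
#' @param reference_sequence reference sequence string.
#' @return list with the member's `label`, `bound` flag and, in reference
#'   coordinates, `covered` (all aligned positions), `missing`, `soft`
#'   (per threshold) and `interface`.
#' @export
map_to_reference <- function(ann, reference_sequence) {
  al <- align_global(ann$sequence, reference_sequence)
  map <- al$map
  remap <- function(pos) {
    v <- map[pos]
    sort(unique(v[!is.na(v)]))
  }
  list(
    label = ann$label,
    bound = ann$bound,
    covered = sort(map[!is.na(map)]),
    missing = remap(ann$missing),
    soft = lapply(ann$soft, remap),
    interface = remap(ann$interface)
  )
}

#' Assemble a cluster around its representative
#'
#' Optionally filters members by maximum resolution, chooses the
#' representative, and maps every member's annotation onto the
#' representative's sequence.
#'
#' @param members list of `ChainAnnotation` (one cluster from
#'   [build_clusters()]).
#' @param structures named list of `ChainStructure` keyed by chain label
#'   (`"entryid_chain"`); must contain the representative. May be `NULL`,
#'   in which case spatial operations on the cluster are unavailable.
#' @param mode representative selection mode, see [select_representative()].
#' @param seed seed for random representative selection.
#' @param max_resolution optional resolution filter in Angstrom applied
#'   before selecting the representative.
#' @return object of class `Cluster`.
#' @export
make_cluster <- function(members, structures = NULL, mode = "best",
                         seed = NULL, max_resolution = NULL) {
  if (!is.null(max_resolution)) {
    keep <- vapply(members, function(a)
      !is.na(a$resolution) && a$resolution <= max_resolution, logical(1))
    if (!any(keep)) return(NULL)
    members <- members[keep]
  }
  rep_idx <- select_representative(members, mode = mode, seed = seed)
  rep_ann <- members[[rep_idx]]
  ref_seq <- rep_ann$sequence
  ref_struct <- if (!is.null(structures)) structures[[rep_ann$label]] else NULL
  mapped <- lapply(members, map_to_reference, reference_sequence = ref_seq)
  structure(
    list(
      cluster_id = rep_ann$label,
      reference_sequence = ref_seq,
      reference_structure = ref_struct,
      reference_annotation = rep_ann,
      members = mapped,
      n_structures = length(members),
      n_unbound = sum(!vapply(mapped, `[[`, logical(1), "bound"))
    ),
    class = "Cluster"
  )
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("<Cluster %s: %d member(s), %d unbound, L_ref=%d>\n",
              x$cluster_id, x$n_structures, x$n_unbound,
              nchar(x$reference_sequence)))
  invisible(x)
}

#' Write cluster definitions as JSON
#'
#' @param clusters list of `Cluster`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_clusters_json <- function(clusters, path) {
  obj <- lapply(clusters, function(cl) list(
    cluster_id = cl$cluster_id,
    reference_sequence = cl$reference_sequence,
    members = vapply(cl$members, `[[`, character(1), "label")
  ))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
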